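# Drug-target matching: join regulon TFs and member genes against a local
# drug-target table, keeping cancer-indication rows in clinical trial phases
# I-IV.

#' Match drugs to regulon TFs and member genes
#'
#' Inner join of the regulons' TFs and member genes against the drug-target
#' table, filtered to cancer-indication rows with a maximum trial phase in
#' I-IV; optionally annotated with each regulon's trajectory label.
#'
#' @param regulons Regulon list (each with `tf`, `genes`, `id`), or a
#'   character vector of TF/gene identifiers.
#' @param drug_target_table data.frame with columns `drug`, `target`,
#'   `indication_class`, `max_trial_phase`.
#' @param trajectory Optional named vector regulon id -> trajectory label.
#' @param trial_phases Admissible phases (default I-IV).
#' @param indication Required indication class (default "cancer").
#' @return data.frame: drug, target, regulon, role (tf/member), phase,
#'   trajectory (possibly zero rows).
#' @export
match_drug_targets <- function(regulons, drug_target_table,
                               trajectory = NULL,
                               trial_phases = c("I", "II", "III", "IV"),
                               indication = "cancer") {
  need <- c("drug", "target", "indication_class", "max_trial_phase")
  missing_cols <- setdiff(need, names(drug_target_table))
  if (length(missing_cols) > 0)
    stop("malformed drug-target table: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  tab <- drug_target_table[drug_target_table$indication_class == indication &
                             drug_target_table$max_trial_phase %in% trial_phases, ,
                           drop = FALSE]
  if (is.character(regulons))
    regulons <- list(list(id = "set", tf = NA_character_, genes = regulons))
  rows <- list()
  for (reg in regulons) {
    rid <- reg$id %||% NA_character_
    members <- data.frame(target = c(reg$tf, reg$genes),
                          role = c("tf", rep("member", length(reg$genes))),
                          stringsAsFactors = FALSE)
    members <- members[!is.na(members$target), , drop = FALSE]
    hit <- merge(tab, members, by = "target")
    if (nrow(hit) > 0) {
      hit$regulon <- rid
      hit$trajectory <- if (!is.null(trajectory)) trajectory[[rid]] %||% NA_character_
        else NA_character_
      rows[[length(rows) + 1]] <- hit
    }
  }
  if (length(rows) == 0)
    return(data.frame(drug = character(0), target = character(0),
                      regulon = character(0), role = character(0),
                      max_trial_phase = character(0),
                      trajectory = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("drug", "target", "regulon", "role", "max_trial_phase", "trajectory")]
}
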