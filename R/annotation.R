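# Per-mutation annotation: region membership, nearest site, pathogenicity tally.

#' The seven functional predictors used for the 0-7 pathogenicity tally
#' @export
PREDICTOR_NAMES <- c("SIFT", "LRT", "MutationTaster", "MutationAssessor",
                     "FATHMM", "MetaSVM", "MetaLR")

#' Pathogenicity score: count of deleterious predictor calls
#'
#' Tallies, over the seven functional predictors, how many call the mutation
#' deleterious. Missing or tolerated calls contribute 0, so the score ranges
#' 0-7.
#'
#' @param calls Named character vector or list mapping predictor name to a
#'   call; names must come from [PREDICTOR_NAMES]. Calls matching one of
#'   `deleterious_labels` (case-insensitive) count as deleterious; anything
#'   else (including `NA` and `""`) does not.
#' @param deleterious_labels Labels treated as deleterious; defaults cover the
#'   common codings `"deleterious"` and `"D"`.
#' @return Integer in 0..7.
#' @examples
#' pathogenicity_score(c(SIFT = "D", LRT = "T", FATHMM = "deleterious"))  # 2
#' @export
pathogenicity_score <- function(calls,
                                deleterious_labels = c("deleterious", "d")) {
  calls <- unlist(calls)
  unknown <- setdiff(names(calls), PREDICTOR_NAMES)
  if (length(unknown) > 0) {
    stop("unknown predictor name(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(PREDICTOR_NAMES, collapse = ", "))
  }
  sum(tolower(trimws(as.character(calls))) %in% tolower(deleterious_labels),
      na.rm = TRUE)
}

#' Annotate mutations with region membership and nearest PTM site
#'
#' Tags every (consequence-filtered) mutation with whether it falls in the
#' merged modification region of its protein, the nearest same-type PTM site
#' and its distance in residues (equidistant sites resolve to the lower
#' position), and — when a predictor-call table is supplied — the 0-7
#' pathogenicity score.
#'
#' @param records Filtered mutation data.frame.
#' @param partitions Named list of `region_partition` keyed by accession
#'   (one PTM type), e.g. from [build_all_partitions()].
#' @param sites PTM-site data.frame of the same type.
#' @param predictor_table Optional data.frame with key columns `accession`,
#'   `position`, `ref_aa`, `alt_aa` plus any subset of the seven predictor
#'   columns ([PREDICTOR_NAMES]).
#' @return Data.frame: the mutation fields plus `in_mod_region`,
#'   `nearest_site`, `nearest_site_type`, `distance_to_site`, and
#'   `pathogenicity_score` (NA without a predictor table or unmatched row).
#' @export
annotate_mutations <- function(records, partitions, sites,
                               predictor_table = NULL) {
  n <- nrow(records)
  in_mod <- logical(n)
  nearest <- rep(NA_integer_, n)
  site_type <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    acc <- records$accession[i]
    pos <- records$position[i]
    part <- partitions[[acc]]
    if (!is.null(part)) in_mod[i] <- pos %in% part$mod_positions
    spos <- sites$position[sites$accession == acc]
    if (length(spos) > 0) {
      d <- abs(spos - pos)
      j <- which(d == min(d))
      j <- j[which.min(spos[j])]   # ties toward the lower position
      nearest[i] <- spos[j]
      dist[i] <- d[j]
      site_type[i] <- sites$ptm_type[sites$accession == acc][j]
    }
  }
  out <- cbind(records,
               data.frame(in_mod_region = in_mod, nearest_site = nearest,
                          nearest_site_type = site_type,
                          distance_to_site = dist,
                          pathogenicity_score = NA_integer_,
                          stringsAsFactors = FALSE))
  if (!is.null(predictor_table)) {
    pred_cols <- intersect(PREDICTOR_NAMES, names(predictor_table))
    if (length(pred_cols) == 0) {
      stop("predictor table carries none of the predictor columns: ",
           paste(PREDICTOR_NAMES, collapse = ", "))
    }
    key <- function(df) paste(df$accession, df$position, df$ref_aa, df$alt_aa,
                              sep = "\r")
    idx <- match(key(out), key(predictor_table))
    matched <- which(!is.na(idx))
    for (i in matched) {
      calls <- as.character(unlist(predictor_table[idx[i], pred_cols]))
      names(calls) <- pred_cols
      out$pathogenicity_score[i] <- pathogenicity_score(calls)
    }
    n_unmatched <- sum(!key(predictor_table) %in% key(out))
    if (n_unmatched > 0) {
      message(sprintf("%d predictor row(s) matched no mutation", n_unmatched))
    }
  }
  rownames(out) <- NULL
  out
}
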