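#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct_target - Ct_reference within the same sample;
#' ddCt subtracts the mean dCt of the calibrator condition (per gene);
#' the relative level is 2^-ddCt. Condition summaries use the Livak
#' convention by default: the point estimate is 2^-(mean ddCt) (a
#' geometric mean of replicate levels), so the calibrator condition is
#' exactly 1; the arithmetic alternative averages the replicate levels
#' directly. The SE is that of the per-replicate relative levels.
#'
#' @param ct Ct table data frame: sample, genotype, stage, replicate,
#'   gene, ct (threshold cycles).
#' @param reference_gene reference transcript (must be measured in every
#'   sample; samples lacking it are dropped with a warning).
#' @param calibrator length-2 character vector (genotype, stage) of the
#'   calibrator condition.
#' @param summary "geometric" (mean ddCt, then exponentiate) or
#'   "arithmetic" (mean of 2^-ddCt).
#' @return data frame: gene, genotype, stage, relative_level, se,
#'   n_replicates.
#' @export
ddct <- function(ct, reference_gene = "OsUbiquitin5",
                 calibrator = c("WT", "ST8"),
                 summary = c("geometric", "arithmetic")) {
  summary <- match.arg(summary)
  req <- c("sample", "genotype", "stage", "replicate", "gene", "ct")
  if (!all(req %in% names(ct)))
    stop("ct table must have columns: ", paste(req, collapse = ", "))
  ref <- ct[ct$gene == reference_gene, ]
  if (nrow(ref) == 0L) stop("reference gene not found: ", reference_gene)
  tgt <- ct[ct$gene != reference_gene, ]

  no_ref <- setdiff(unique(tgt$sample), unique(ref$sample))
  if (length(no_ref) > 0L) {
    warning("samples without reference measurements dropped: ",
            paste(no_ref, collapse = ", "))
    tgt <- tgt[!tgt$sample %in% no_ref, ]
  }
  tgt$dct <- tgt$ct - ref$ct[match(tgt$sample, ref$sample)]

  cal <- tgt$genotype == calibrator[1L] & tgt$stage == calibrator[2L]
  if (!any(cal)) stop("calibrator condition not present: ",
                      paste(calibrator, collapse = " / "))
  cal_mean <- tapply(tgt$dct[cal], tgt$gene[cal], mean)
  if (!all(unique(tgt$gene) %in% names(cal_mean)))
    stop("calibrator condition missing for some genes")
  tgt$ddct <- tgt$dct - cal_mean[tgt$gene]
  tgt$rel <- 2^(-tgt$ddct)

  grp <- interaction(tgt$gene, tgt$genotype, tgt$stage, drop = TRUE)
  first <- !duplicated(grp)
  key <- as.character(grp[first])
  out <- data.frame(gene = tgt$gene[first], genotype = tgt$genotype[first],
                    stage = tgt$stage[first], stringsAsFactors = FALSE)
  out$relative_level <- as.numeric(
    if (summary == "geometric") 2^(-tapply(tgt$ddct, grp, mean)[key])
    else tapply(tgt$rel, grp, mean)[key])
  n <- tapply(tgt$rel, grp, length)[key]
  sdv <- tapply(tgt$rel, grp, sd)[key]
  out$se <- as.numeric(sdv / sqrt(n))
  out$n_replicates <- as.integer(n)
  rownames(out) <- NULL
  out[order(out$gene, out$genotype, out$stage), ]
}
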