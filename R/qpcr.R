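#' Relative expression by the 2^-dCt method
#'
#' For every sample and gene, dCt = Ct_gene - Ct_reference_gene (the
#' housekeeping gene, e.g. beta-actin) and expression = 2^-dCt. Technical
#' replicates (duplicate rows for the same sample/condition/gene) are
#' averaged on the Ct scale first. Samples missing the reference gene are
#' skipped with a message.
#'
#' @param table data.frame with columns `sample_id`, `gene`, `ct` and
#'   optionally `condition`.
#' @param reference_gene housekeeping gene name.
#' @return data.frame with sample_id, condition, gene, delta_ct, expression.
#' @export
delta_ct <- function(table, reference_gene = "BACTIN") {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(table)))
  if (!any(table$gene == reference_gene))
    stop("reference gene '", reference_gene, "' absent from table")
  if (is.null(table$condition)) table$condition <- "all"
  # average technical replicates on the Ct scale
  agg <- stats::aggregate(ct ~ sample_id + condition + gene, data = table,
                          FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg[c("sample_id", "condition")],
                                     drop = TRUE), function(d) {
    ref <- d$ct[d$gene == reference_gene]
    if (length(ref) != 1L) {
      message("skipping sample '", d$sample_id[1],
              "': reference gene missing")
      return(NULL)
    }
    g <- d[d$gene != reference_gene, , drop = FALSE]
    data.frame(sample_id = g$sample_id, condition = g$condition,
               gene = g$gene, delta_ct = g$ct - ref,
               expression = 2^-(g$ct - ref), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fold change by the 2^-ddCt method
#'
#' ddCt = dCt_sample - mean(dCt of the reference condition for that gene);
#' fold change = 2^-ddCt relative to the reference (control) condition.
#'
#' @param table data.frame with `sample_id`, `condition`, `gene`, `ct`.
#' @param reference_gene housekeeping gene name.
#' @param reference_condition control condition name (e.g. `"co"`).
#' @return data.frame with sample_id, condition, gene, delta_ct,
#'   delta_delta_ct, fold_change.
#' @export
delta_delta_ct <- function(table, reference_gene = "BACTIN",
                           reference_condition = "co") {
  stopifnot("condition" %in% names(table))
  if (!any(table$condition == reference_condition))
    stop("reference condition '", reference_condition, "' absent from table")
  dct <- delta_ct(table, reference_gene)
  ref_means <- tapply(dct$delta_ct[dct$condition == reference_condition],
                      dct$gene[dct$condition == reference_condition], mean)
  if (!all(dct$gene %in% names(ref_means)))
    stop("some genes lack the reference condition: ",
         paste(setdiff(unique(dct$gene), names(ref_means)), collapse = ", "))
  dct$delta_delta_ct <- dct$delta_ct - as.numeric(ref_means[dct$gene])
  dct$fold_change <- 2^-dct$delta_delta_ct
  dct
}
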