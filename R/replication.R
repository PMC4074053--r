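# Readers for externally produced score/classification tables in the
# interchange schema (gene, feature, rep1..rep3 Z-scores; per-gene
# quadrant records), so published supplementary tables exported to TSV can
# be re-counted with the package's hit-calling and quadrant logic.

#' Read a triplicate Z-score table
#'
#' Expects a TSV with columns `gene`, `feature`, `rep1`, `rep2`, `rep3`
#' (one row per gene-feature), the interchange schema for screen-wide
#' Z-scores.
#'
#' @param path TSV path.
#' @return A `zscore_matrix` array (gene x feature x replicate).
#' @export
read_zscore_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("gene", "feature", "rep1", "rep2", "rep3")
  missing <- setdiff(req, colnames(tab))
  if (length(missing)) stopf("missing column %s", missing[1])
  genes <- unique(tab$gene)
  feats <- unique(tab$feature)
  arr <- array(NA_real_, dim = c(length(genes), length(feats), 3),
               dimnames = list(gene = genes, feature = feats,
                               replicate = paste0("rep", 1:3)))
  idx <- cbind(match(tab$gene, genes), match(tab$feature, feats))
  for (r in 1:3) arr[cbind(idx, r)] <- tab[[paste0("rep", r)]]
  structure(arr, class = c("zscore_matrix", "array"))
}

#' Write a `zscore_matrix` in the interchange schema
#' @param z A `zscore_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_zscore_table <- function(z, path) {
  dn <- dimnames(z)
  tab <- expand.grid(gene = dn$gene, feature = dn$feature,
                     stringsAsFactors = FALSE)
  for (r in seq_len(dim(z)[3]))
    tab[[paste0("rep", r)]] <- as.vector(z[, , r])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count quadrant membership of secondary records
#' @param records A `secondary_records` data frame (or any data frame with
#'   a `quadrant` column).
#' @return Named integer vector over quadrants 1-4 and `"null"`.
#' @export
quadrant_counts <- function(records) {
  q <- factor(records$quadrant, levels = c("1", "2", "3", "4", "null"))
  table(q)
}
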