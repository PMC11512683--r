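#' Run the full single-cell genotyping and clonal-analysis pipeline
#'
#' Convenience wrapper chaining threshold derivation, per-amplicon and
#' consensus calling, SNP-based ADO rescue, clone-tree inference and cell
#' assignment.
#'
#' @param dataset A \code{genotyping_dataset}.
#' @param config A [run_config()].
#' @param false_positive_rate,ado_rate Error parameters of the tree
#'   likelihood (see [infer_clone_tree()]).
#' @return List: \code{thresholds}, \code{calls} (consensus table with ADO
#'   flags and clone labels), \code{ado_report}, \code{tree_fit},
#'   \code{assignments}.
#' @export
run_pipeline <- function(dataset, config = run_config(),
                         false_positive_rate = 0.01, ado_rate = 0.02) {
  thresholds <- derive_thresholds_all(dataset, config)
  calls <- call_genotypes(dataset, thresholds, config)
  ado <- ado_analysis(dataset, calls, config)
  calls <- ado$calls
  mat <- genotype_matrix(calls)
  tree_fit <- infer_clone_tree(mat, false_positive_rate, ado_rate)
  assignments <- assign_cells(mat, tree_fit$tree,
                              max_ancestral_ado = config$max_ancestral_ado)
  calls$clone_id <- assignments$clone_id[match(calls$cell_id,
                                               assignments$cell_id)]
  list(thresholds = thresholds, calls = calls, ado_report = ado$report,
       tree_fit = tree_fit, assignments = assignments)
}
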