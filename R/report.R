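#' Run the full downstream analysis and write a report bundle
#'
#' Orchestrates every stage the package implements over whatever inputs are
#' supplied: expressed-gene filtering, stage-specificity tables at the
#' 50/80/90% criteria, the sample dendrogram (Newick), PAM clustering of
#' gene trajectories with silhouettes and medoid curves, the fold-change
#' category table, the transcription-factor screen, isoform-switch
#' detection, the protein composition screen, and cluster label-fraction
#' enrichment. Stages whose inputs are absent are skipped with a notice in
#' the manifest. All outputs are plain TSV/JSON/Newick, sorted
#' deterministically, so re-running with identical inputs reproduces them
#' byte for byte.
#'
#' @param expression an [expression_matrix()] (mandatory)
#' @param outdir output directory (created if needed)
#' @param isoforms optional [isoform_matrix()]
#' @param annotations optional `annotation_set` ([read_annotation_lists()]);
#'   label sets named `tf_dna_binding` and `arthropod_restricted` feed the
#'   TF screen and the cluster enrichment stage
#' @param de optional `de_result` ([read_de_table()])
#' @param proteins optional `protein_set`
#' @param k clusters for the trajectory PAM (default 16)
#' @param floor expressed-gene FPKM floor (default 1)
#' @param alphas stage-specificity thresholds (default c(0.5, 0.8, 0.9))
#' @param top_n per-time top-expressed genes (default 20)
#' @param q_cut DE significance cutoff (default 0.05)
#' @param min_fpkm,min_fold TF screen thresholds (defaults 30 and 4)
#' @param min_switch_fpkm,min_delta switch-detection thresholds (defaults 1
#'   and 0.25)
#' @param max_cluster_genes cap on genes entering the O(n^2) trajectory
#'   clustering; the highest-total-FPKM genes are kept when exceeded
#'   (default 1000)
#' @return (invisibly) a list with every stage's in-memory result and the
#'   manifest
#' @export
run_report <- function(expression, outdir,
                       isoforms = NULL, annotations = NULL, de = NULL,
                       proteins = NULL,
                       k = 16, floor = 1, alphas = c(0.5, 0.8, 0.9),
                       top_n = 20, q_cut = 0.05,
                       min_fpkm = 30, min_fold = 4,
                       min_switch_fpkm = 1, min_delta = 0.25,
                       max_cluster_genes = 1000) {
  if (missing(expression) || !inherits(expression, "expr_matrix"))
    stop("an expression matrix is mandatory")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  skipped <- character()
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  expressed <- sort(filter_expressed(expression, floor = floor))
  res$expressed <- expressed
  tsv(data.frame(gene_id = expressed), "expressed_genes.tsv")

  prof <- specificity_fractions(expression)
  spec_rows <- list()
  for (a in alphas) {
    cs <- count_stage_specific(prof, alpha = a)
    for (tnm in names(cs$genes)) {
      g <- cs$genes[[tnm]]
      spec_rows[[length(spec_rows) + 1L]] <- data.frame(
        alpha = a, time = as.numeric(tnm), n = length(g),
        genes = paste(sort(g), collapse = ","))
    }
  }
  res$specificity <- do.call(rbind, spec_rows)
  tsv(res$specificity, "stage_specific_genes.tsv")

  top <- top_expressed_union(expression, n = top_n)
  res$top_union <- top$union
  tsv(data.frame(gene_id = top$union), "top_expressed_union.tsv")

  sd_mat <- sample_distance_matrix(expression)
  build_dendrogram(sd_mat, newick = file.path(outdir,
                                              "sample_dendrogram.nwk"))
  res$sample_distances <- sd_mat

  cl_genes <- expressed
  if (!is.null(de)) {
    sig <- sort(unique(de$gene[de$q < q_cut]))
    cl_genes <- intersect(cl_genes, sig)
  }
  if (length(cl_genes) > max_cluster_genes) {
    tot <- rowSums(expression$fpkm[cl_genes, , drop = FALSE])
    cl_genes <- cl_genes[order(-tot)][seq_len(max_cluster_genes)]
    cl_genes <- sort(cl_genes)
  }
  if (length(cl_genes) >= max(3, k)) {
    d <- gene_trajectory_distances(expression, cl_genes)
    fit <- silhouette_scores(pam_fit(d, k = min(k, length(cl_genes))), d)
    res$clusters <- fit
    asn <- data.frame(gene_id = names(fit$assignment),
                      cluster = unname(fit$assignment),
                      silhouette = unname(fit$silhouette))
    asn <- asn[order(asn$gene_id), ]
    tsv(asn, "cluster_assignment.tsv")
    tsv(medoid_curves(fit, expression), "medoid_curves.tsv")
  } else skipped <- c(skipped, "clustering: too few eligible genes")

  if (!is.null(de)) {
    res$fold_table <- fold_category_table(expression, de, q_cut = q_cut)
    tsv(res$fold_table, "fold_category_table.tsv")
  } else skipped <- c(skipped, "fold_category_table: no DE table")

  tf <- annotations$labels$tf_dna_binding
  if (!is.null(tf)) {
    res$tf <- tf_candidates(expression, tf, min_fpkm = min_fpkm,
                            min_fold = min_fold)
    tsv(res$tf$stage2, "tf_candidates.tsv")
  } else skipped <- c(skipped, "tf_candidates: no tf_dna_binding label set")

  if (!is.null(isoforms)) {
    res$switches <- detect_switches(isoforms, min_fpkm = min_switch_fpkm,
                                    min_delta = min_delta)
    tsv(res$switches, "isoform_switches.tsv")
  } else skipped <- c(skipped, "switches: no isoform matrix")

  if (!is.null(proteins)) {
    res$composition <- screen_candidates(proteins)
    tsv(res$composition$table, "composition_screen.tsv")
  } else skipped <- c(skipped, "composition: no protein set")

  arth <- annotations$labels$arthropod_restricted
  if (!is.null(arth) && !is.null(res$clusters)) {
    res$enrichment <- cluster_label_fractions(res$clusters, arth)
    tsv(res$enrichment, "cluster_label_fractions.tsv")
  } else skipped <- c(skipped,
                      "enrichment: no arthropod_restricted label set")

  manifest <- list(
    package = "cuticleCourse",
    version = as.character(utils::packageVersion("cuticleCourse")),
    thresholds = list(k = k, floor = floor, alphas = alphas, top_n = top_n,
                      q_cut = q_cut, min_fpkm = min_fpkm,
                      min_fold = min_fold,
                      min_switch_fpkm = min_switch_fpkm,
                      min_delta = min_delta),
    n_genes = nrow(expression$fpkm),
    times = expression$times,
    skipped = skipped)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
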