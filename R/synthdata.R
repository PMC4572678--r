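#' Specification for a synthetic two-class expression dataset
#'
#' The generator emulates a two-class expression study of the shape used
#' throughout this package's validation: a 20-versus-10 sample design
#' with a moderate number of differentially expressed gene clusters
#' planted in a background of null genes. Background genes are iid
#' Gaussian; each planted cluster shares a latent factor
#' (`x = sqrt(rho) * f_cluster + sqrt(1 - rho) * eps`, giving exact
#' target pairwise correlation `rho`) and a class-1 mean shift of
#' `effect` noise-sd units.
#'
#' @param n_genes total gene count (default 1000).
#' @param n0,n1 per-class sample counts (defaults 20 control, 10
#'   treatment).
#' @param k_true number of planted DE clusters (default 5).
#' @param genes_per_cluster genes per planted cluster (default 20);
#'   `k_true * genes_per_cluster` must not exceed `n_genes`.
#' @param effect class-1 mean shift in noise-sd units (default 2).
#' @param rho within-cluster pairwise correlation in \[0, 1) (default
#'   0.7).
#' @param noise_sd background standard deviation (default 1).
#' @param mu_bg background mean, on a log2-intensity-like scale
#'   (default 7).
#' @param seed integer seed.
#' @return a validated `"synth_spec"` list.
#' @export
synth_spec <- function(n_genes = 1000, n0 = 20, n1 = 10, k_true = 5,
                       genes_per_cluster = 20, effect = 2, rho = 0.7,
                       noise_sd = 1, mu_bg = 7, seed = 1) {
  if (k_true * genes_per_cluster > n_genes)
    stop("k_true * genes_per_cluster exceeds n_genes")
  if (effect < 0) stop("effect must be >= 0")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (n0 < 2 || n1 < 2) stop("each class needs at least 2 samples")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_genes = n_genes, n0 = n0, n1 = n1, k_true = k_true,
                 genes_per_cluster = genes_per_cluster, effect = effect,
                 rho = rho, noise_sd = noise_sd, mu_bg = mu_bg,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic dataset with known exemplar ground truth
#'
#' @param spec a [synth_spec()].
#' @param intensity_scale if TRUE, values are exponentiated base 2 so the
#'   matrix is strictly positive and the log2 preprocessing paths can be
#'   exercised (default FALSE: values stay on the simulated log-like
#'   scale).
#' @return list with `data` (an [apkl_dataset()]) and `truth` (list:
#'   `de_genes` per planted cluster, `cluster` assignment vector over all
#'   genes with 0 = background, and the class labels).
#' @examples
#' sim <- synth_dataset(synth_spec(n_genes = 100, seed = 42))
#' sim$data
#' @export
synth_dataset <- function(spec, intensity_scale = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n0 + spec$n1
  cls <- c(rep(0L, spec$n0), rep(1L, spec$n1))
  sample_ids <- sprintf("s%02d", seq_len(n))
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  x <- matrix(stats::rnorm(spec$n_genes * n, mean = spec$mu_bg,
                           sd = spec$noise_sd),
              spec$n_genes, n, dimnames = list(gene_ids, sample_ids))
  cluster <- integer(spec$n_genes)
  de_genes <- vector("list", spec$k_true)
  if (spec$k_true > 0) {
    shift <- spec$effect * spec$noise_sd
    for (cc in seq_len(spec$k_true)) {
      rows <- ((cc - 1L) * spec$genes_per_cluster + 1L):
        (cc * spec$genes_per_cluster)
      cluster[rows] <- cc
      de_genes[[cc]] <- gene_ids[rows]
      f <- stats::rnorm(n)                       # shared latent factor
      eps <- matrix(stats::rnorm(length(rows) * n), length(rows), n)
      core <- sqrt(spec$rho) * matrix(f, length(rows), n, byrow = TRUE) +
        sqrt(1 - spec$rho) * eps
      x[rows, ] <- spec$mu_bg + spec$noise_sd * core +
        shift * matrix(cls, length(rows), n, byrow = TRUE)
    }
  }
  if (intensity_scale) x <- 2^x
  labels <- data.frame(sample_id = sample_ids, title = sample_ids,
                       type = cls, stringsAsFactors = FALSE)
  list(data = apkl_dataset(x, labels),
       truth = list(de_genes = de_genes,
                    cluster = stats::setNames(cluster, gene_ids),
                    labels = stats::setNames(cls, sample_ids)))
}

#' Write a synthetic dataset to a directory as TSV files
#'
#' Emits `exprs.tsv` and `labels.tsv` in the formats read by
#' [load_dataset()].
#'
#' @param sim a [synth_dataset()] result.
#' @param dir output directory (created if absent).
#' @return character vector of the two paths written, invisibly.
#' @export
write_synth_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ep <- file.path(dir, "exprs.tsv")
  lp <- file.path(dir, "labels.tsv")
  write_expression_matrix(sim$data$exprs, ep)
  write_class_labels(sim$data$labels, lp)
  invisible(c(ep, lp))
}
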