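# Ancestry and sex inference: LD pruning, PCA on standardized genotype
# dosages, nearest-neighbor population classification against labelled
# references, and X-heterozygosity sex calls.

#' Greedy windowed LD pruning
#'
#' Slides a window over the variants (left to right, `step` variants at a
#' time); within each window, for every pair still retained whose squared
#' Pearson correlation of dosages exceeds `r2_max`, the later variant is
#' dropped.  Monomorphic pairs have undefined r-squared and are never
#' dropped for it.
#'
#' @param genotypes Sample x variant dosage matrix.
#' @param r2_max Maximum allowed squared correlation, in (0, 1].
#' @param window,step Window size (>= 2) and step, in variants.
#' @return Integer indices of retained variants (named if the matrix has
#'   column names).  Fewer than 2 variants are returned unchanged.
#' @export
ld_prune <- function(genotypes, r2_max = 0.2, window = 50L, step = 5L) {
  m <- ncol(genotypes)
  if (m < 2) return(stats::setNames(seq_len(m), colnames(genotypes)))
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0, 1]")
  if (window < 2) stop("window must be >= 2")
  keep <- rep(TRUE, m)
  starts <- unique(c(seq(1L, max(1L, m - window + 1L), by = step)))
  for (s in starts) {
    idx <- which(keep)
    idx <- idx[idx >= s & idx < s + window]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(stats::cor(genotypes[, idx, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    for (a in seq_len(length(idx) - 1L)) {
      if (!keep[idx[a]]) next
      for (b in (a + 1L):length(idx)) {
        if (keep[idx[b]] && r2[a, b] > r2_max) keep[idx[b]] <- FALSE
      }
    }
  }
  stats::setNames(which(keep), colnames(genotypes)[keep])
}

#' Fit a PCA model on reference genotypes
#'
#' Dosages are standardized per variant by center 2*p and scale
#' sqrt(2*p*(1-p)), p being the reference alt-allele frequency; the
#' components are the top right-singular directions of the standardized
#' matrix.  Monomorphic variants are dropped and recorded.  Study samples
#' are later projected with the reference frequencies (see
#' [predict.tpmt_pca()]), so study structure never leaks into the model.
#'
#' @param genotypes Reference sample x variant dosage matrix (>= 2 samples,
#'   >= 2 polymorphic variants).
#' @param n_components Number of components to keep.
#' @return A `tpmt_pca`: kept variant indices/names, center, scale,
#'   loadings (variant x component), reference scores, dropped variants.
#' @export
fit_pca <- function(genotypes, n_components = 10L) {
  if (nrow(genotypes) < 2) stop("need >= 2 reference samples")
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  v <- apply(genotypes, 2, stats::var)
  poly <- p > 0 & p < 1 & !is.na(v) & v > 0
  if (sum(poly) < 2) stop("all variants monomorphic")
  center <- 2 * p[poly]
  scale <- sqrt(2 * p[poly] * (1 - p[poly]))
  z <- sweep(sweep(genotypes[, poly, drop = FALSE], 2, center), 2, scale, "/")
  z[is.na(z)] <- 0
  k <- min(n_components, nrow(z) - 1L, ncol(z))
  sv <- svd(z, nu = 0, nv = k)
  loadings <- sv$v
  rownames(loadings) <- colnames(genotypes)[poly]
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(kept = which(poly), center = center, scale = scale,
                 loadings = loadings, n_components = k,
                 scores = z %*% loadings,
                 dropped = which(!poly)),
            class = "tpmt_pca")
}

#' Project genotypes onto a fitted PCA model
#'
#' @param object A `tpmt_pca`.
#' @param newdata Sample x variant dosage matrix covering the model's kept
#'   variants (matched by column index if unnamed).
#' @param ... Unused.
#' @return Sample x component score matrix.
#' @export
predict.tpmt_pca <- function(object, newdata, ...) {
  g <- newdata[, object$kept, drop = FALSE]
  z <- sweep(sweep(g, 2, object$center), 2, object$scale, "/")
  z[is.na(z)] <- 0
  z %*% object$loadings
}

#' @export
print.tpmt_pca <- function(x, ...) {
  cat(sprintf("PCA model: %d variants (%d monomorphic dropped), %d components\n",
              length(x$kept), length(x$dropped), x$n_components))
  invisible(x)
}

#' Classify samples by k nearest reference neighbors in PC space
#'
#' Majority label among the k Euclidean nearest labelled reference
#' samples; ties are broken by the label of the single nearest neighbor.
#'
#' @param study_scores,ref_scores Score matrices from the same PCA model.
#' @param ref_labels Population label per reference sample.
#' @param k Neighbor count, 1 <= k <= number of references.
#' @return data.frame(sample, population, super_group) with a `votes`
#'   attribute (sample x label count matrix).
#' @export
classify_population <- function(study_scores, ref_scores, ref_labels,
                                k = 9L) {
  if (nrow(ref_scores) == 0) stop("empty reference set")
  if (k < 1 || k > nrow(ref_scores)) stop("k must be in [1, n_ref]")
  labs <- sort(unique(ref_labels))
  votes <- matrix(0L, nrow(study_scores), length(labs),
                  dimnames = list(rownames(study_scores), labs))
  assigned <- character(nrow(study_scores))
  rs2 <- rowSums(ref_scores^2)
  for (i in seq_len(nrow(study_scores))) {
    d2 <- rs2 - 2 * drop(ref_scores %*% study_scores[i, ])
    ord <- order(d2)
    nb <- ref_labels[ord[seq_len(k)]]
    tab <- table(nb)
    votes[i, names(tab)] <- as.integer(tab)
    winners <- names(tab)[tab == max(tab)]
    assigned[i] <- if (length(winners) == 1L) winners else ref_labels[ord[1L]]
  }
  out <- data.frame(sample = rownames(study_scores) %||%
                      seq_len(nrow(study_scores)),
                    population = assigned,
                    super_group = super_group_of(assigned),
                    stringsAsFactors = FALSE)
  attr(out, "votes") <- votes
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Infer sex from X-chromosome heterozygosity
#'
#' Per sample, the inbreeding-style statistic F = 1 - observed/expected X
#' heterozygosity, with expected heterozygosity the mean over markers of
#' 2*p*(1-p) (p from the full sample).  Calls: male if F > 0.8, female if
#' F < 0.2, otherwise undetermined (as is an expected heterozygosity of 0).
#'
#' @param x_genotypes Sample x X-marker dosage matrix (0/1/2).
#' @param male_min,female_max F thresholds for male and female calls.
#' @return data.frame(sample, f_stat, sex).
#' @export
infer_sex <- function(x_genotypes, male_min = 0.8, female_max = 0.2) {
  if (ncol(x_genotypes) < 1) stop("need >= 1 X marker")
  p <- colMeans(x_genotypes, na.rm = TRUE) / 2
  exp_het <- mean(2 * p * (1 - p))
  obs_het <- rowMeans(x_genotypes == 1L, na.rm = TRUE)
  if (exp_het == 0) {
    f <- rep(NA_real_, nrow(x_genotypes))
  } else {
    f <- 1 - obs_het / exp_het
  }
  sex <- ifelse(is.na(f), "undetermined",
         ifelse(f > male_min, "male",
         ifelse(f < female_max, "female", "undetermined")))
  data.frame(sample = rownames(x_genotypes) %||% seq_len(nrow(x_genotypes)),
             f_stat = f, sex = sex, stringsAsFactors = FALSE)
}
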