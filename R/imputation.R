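# Reference-panel imputation with a haplotype-copying (Li-Stephens style)
# hidden Markov model.  Hidden states are the K panel haplotypes; between
# adjacent markers a copying haplotype is kept with probability
# 1 - rho + rho/K and switched to any specific other with rho/K; typed
# markers emit the observed allele with probability 1 - eps on a match and
# eps on a mismatch; untyped markers emit nothing.  The locus spans ~27 kb
# so a single per-interval switch probability is used (no genetic map).
# Forward/backward vectors are rescaled at every marker, keeping the
# computation in the linear domain without underflow.

#' Imputation parameters
#'
#' @param rho Per-interval switch probability in [0, 1).
#' @param eps Per-marker copying-error probability in (0, 0.5).
#' @param info_threshold Minimum info score for a variant to be retained
#'   (inclusive); default 0.9.
#' @param call_threshold Minimum posterior probability for a hard genotype
#'   call; default 0.9.
#' @return List of validated parameters.
#' @export
imputation_params <- function(rho = 0.01, eps = 0.001,
                              info_threshold = 0.9, call_threshold = 0.9) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (eps <= 0 || eps >= 0.5) stop("eps must be in (0, 0.5)")
  if (info_threshold < 0 || info_threshold > 1)
    stop("info_threshold must be in [0, 1]")
  if (call_threshold < 0 || call_threshold > 1)
    stop("call_threshold must be in [0, 1]")
  list(rho = rho, eps = eps, info_threshold = info_threshold,
       call_threshold = call_threshold)
}

#' Impute one study haplotype against a phased reference panel
#'
#' Runs the scaled forward-backward recursion over the panel haplotypes
#' and returns, at every panel variant, the posterior probability that the
#' study haplotype carries the alt allele: the state posterior mass on
#' panel haplotypes carrying alt at that variant.
#'
#' @param typed Named vector of observed alleles (0/1) at the probed
#'   markers; names are variant ids and must be a subset of the panel's
#'   variants.  NA entries are treated as untyped.
#' @param panel A `haplotype_panel`.
#' @param params [imputation_params()].
#' @return Named numeric vector: posterior alt-allele probability at each
#'   panel variant, in panel variant order.
#' @export
impute_haplotype <- function(typed, panel, params = imputation_params()) {
  H <- panel$haplotypes
  K <- nrow(H); M <- ncol(H)
  if (K == 0) stop("empty panel")
  typed <- typed[!is.na(typed)]
  if (length(typed) && !all(names(typed) %in% colnames(H)))
    stop("typed variant absent from panel: ",
         paste(setdiff(names(typed), colnames(H)), collapse = ", "))
  obs <- rep(NA_integer_, M)
  obs[match(names(typed), colnames(H))] <- as.integer(typed)
  rho <- params$rho; eps <- params$eps

  emis <- function(m) {
    if (is.na(obs[m])) rep(1, K)
    else ifelse(H[, m] == obs[m], 1 - eps, eps)
  }
  # forward, rescaled at every marker
  alpha <- matrix(NA_real_, M, K)
  scal <- numeric(M)
  a <- rep(1 / K, K) * emis(1L)
  scal[1] <- sum(a); alpha[1, ] <- a / scal[1]
  if (M > 1) for (m in 2:M) {
    a <- (1 - rho) * alpha[m - 1L, ] + rho / K  # sum(alpha[m-1,]) == 1
    a <- a * emis(m)
    scal[m] <- sum(a); alpha[m, ] <- a / scal[m]
  }
  # backward, using the forward scaling factors
  beta <- matrix(NA_real_, M, K)
  beta[M, ] <- 1
  if (M > 1) for (m in (M - 1L):1L) {
    v <- emis(m + 1L) * beta[m + 1L, ]
    beta[m, ] <- ((1 - rho) * v + (rho / K) * sum(v)) / scal[m + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  p_alt <- rowSums(gamma * t(H))
  stats::setNames(p_alt, colnames(H))
}

#' Combine two haplotype posteriors into genotype probabilities
#'
#' Under independence of the two haplotype imputations,
#' (p0, p1, p2) = ((1-a)(1-b), a(1-b) + b(1-a), ab).
#'
#' @param a,b Posterior alt-allele probabilities in [0, 1] (vectors allowed).
#' @return Matrix with columns p0, p1, p2 (rows sum to 1).
#' @export
genotype_posteriors <- function(a, b) {
  if (any(a < 0 | a > 1 | b < 0 | b > 1)) stop("probabilities must be in [0,1]")
  cbind(p0 = (1 - a) * (1 - b), p1 = a * (1 - b) + b * (1 - a), p2 = a * b)
}

#' Imputation info score for one variant
#'
#' The ratio-of-variances imputation quality measure: with per-sample
#' expected dosage e_i = p_i1 + 2 p_i2 and second moment
#' f_i = p_i1 + 4 p_i2, the estimated alt frequency is
#' theta = sum(e_i) / 2N and
#' info = 1 - sum(f_i - e_i^2) / (2N theta (1 - theta)).
#' info = 1 when theta is 0 or 1 (no variance to explain); the result is
#' clamped to [0, 1].
#'
#' @param probs N x 3 matrix of genotype posteriors (p0, p1, p2).
#' @return List: info, theta (estimated alt frequency), n.
#' @export
info_score <- function(probs) {
  probs <- rbind(probs)
  n <- nrow(probs)
  if (n < 1) stop("empty input")
  e <- probs[, 2] + 2 * probs[, 3]
  f <- probs[, 2] + 4 * probs[, 3]
  theta <- sum(e) / (2 * n)
  info <- if (theta <= 0 || theta >= 1) 1
          else 1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
  list(info = min(1, max(0, info)), theta = theta, n = n)
}

#' Filter variants by info score
#'
#' Retention is inclusive: a variant with info exactly at the threshold is
#' kept.
#'
#' @param infos data.frame with columns `variant_id` and `info`.
#' @param threshold Minimum info score in [0, 1].
#' @return Character vector of retained variant ids.
#' @export
filter_variants <- function(infos, threshold = 0.9) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  infos$variant_id[infos$info >= threshold]
}

#' Hard genotype call from a posterior triplet
#'
#' argmax of (p0, p1, p2) if the maximum reaches `call_threshold`; exact
#' ties and sub-threshold maxima yield a no-call (NA).
#'
#' @param probs N x 3 posterior matrix.
#' @param call_threshold Minimum posterior for a call.
#' @return Integer vector of alt-allele counts 0/1/2, NA for no-call.
#' @export
best_guess_genotype <- function(probs, call_threshold = 0.9) {
  probs <- rbind(probs)
  vapply(seq_len(nrow(probs)), function(i) {
    p <- probs[i, ]
    mx <- max(p)
    if (mx < call_threshold || sum(p == mx) > 1L) NA_integer_
    else which.max(p) - 1L
  }, integer(1))
}

#' Impute a typed cohort chip against a reference panel
#'
#' Runs [impute_haplotype()] for both haplotypes of every sample on one
#' chip, combines them into genotype posteriors, and scores every variant.
#'
#' @param chip_data One element of `simulate_cohort()$typed`: list with
#'   `sample_ids`, `hapA`, `hapB` (phased typed alleles, NA at unprobed
#'   markers).
#' @param panel A `haplotype_panel`.
#' @param params [imputation_params()].
#' @return List: `posteriors` (list of p0/p1/p2 sample x variant
#'   matrices), `dosage`, `info` data.frame (variant_id, info, theta, n),
#'   `sample_ids`.
#' @export
impute_chip <- function(chip_data, panel, params = imputation_params()) {
  vids <- colnames(panel$haplotypes)
  n <- length(chip_data$sample_ids)
  pA <- matrix(NA_real_, n, length(vids), dimnames = list(NULL, vids))
  pB <- pA
  for (i in seq_len(n)) {
    tA <- chip_data$hapA[i, ]; tB <- chip_data$hapB[i, ]
    pA[i, ] <- impute_haplotype(tA[!is.na(tA)], panel, params)
    pB[i, ] <- impute_haplotype(tB[!is.na(tB)], panel, params)
  }
  p0 <- (1 - pA) * (1 - pB)
  p2 <- pA * pB
  p1 <- 1 - p0 - p2
  info <- do.call(rbind, lapply(seq_along(vids), function(j) {
    s <- info_score(cbind(p0[, j], p1[, j], p2[, j]))
    data.frame(variant_id = vids[j], info = s$info, theta = s$theta,
               n = s$n, stringsAsFactors = FALSE)
  }))
  list(posteriors = list(p0 = p0, p1 = p1, p2 = p2),
       dosage = p1 + 2 * p2, info = info,
       sample_ids = chip_data$sample_ids)
}
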