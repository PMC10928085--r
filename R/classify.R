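# Probabilistic subcellular localization: marker pruning, T-augmented
# Gaussian mixture fitting on marker profiles, MAP allocation with an
# outlier component, and expected-FDR reporting.

# Separation score: mean pairwise distance between class centroids over
# mean distance of markers to their own centroid. Inf when classes are
# internally exact.
separation_score <- function(X, labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) < 2L) stop("need at least 2 classes")
  centroids <- t(vapply(cls, function(c)
    colMeans(X[labels == c, , drop = FALSE]), numeric(ncol(X))))
  between <- mean(stats::dist(centroids))
  within <- mean(sqrt(rowSums((X - centroids[match(labels, cls), ,
                                             drop = FALSE])^2)))
  if (within == 0) Inf else between / within
}

#' Prune organelle markers to maximize between-class separation
#'
#' Seeded stochastic search: repeatedly proposes removing one marker from
#' a class above the size floor and accepts the removal when the
#' normalized separation score (mean between-class centroid distance over
#' mean within-class distance to centroid) strictly increases. The search
#' stops after `max_stall` consecutive non-improving proposals or
#' `budget` total proposals.
#'
#' @param X Marker profile matrix (markers x features), rownames =
#'   accessions.
#' @param labels Compartment label per marker.
#' @param floor Minimum markers per compartment after pruning (default 6).
#' @param budget Total proposal budget (default 500).
#' @param max_stall Consecutive rejections that end the search
#'   (default 100).
#' @param seed Integer seed for the proposal sequence.
#' @return List with `keep` (logical per input marker), `labels` (kept
#'   labels), `score`, `n_removed`.
#' @export
prune_markers <- function(X, labels, floor = 6, budget = 500,
                          max_stall = 100, seed = 1) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) < 2L) stop("need at least 2 compartments")
  if (any(counts < floor))
    stop("compartment(s) below marker floor at input: ",
         paste(names(counts)[counts < floor], collapse = ", "))
  keep <- rep(TRUE, nrow(X))
  score <- separation_score(X, labels)
  with_seed(seed, {
    stall <- 0L
    for (it in seq_len(budget)) {
      if (stall >= max_stall) break
      counts <- table(labels[keep])
      movable <- which(keep & counts[labels] > floor)
      if (length(movable) == 0L) break
      cand <- movable[sample.int(length(movable), 1L)]
      keep2 <- keep; keep2[cand] <- FALSE
      s2 <- separation_score(X[keep2, , drop = FALSE], labels[keep2])
      if (s2 > score) {
        keep <- keep2; score <- s2; stall <- 0L
      } else stall <- stall + 1L
    }
  })
  list(keep = keep, labels = labels[keep], score = score,
       n_removed = sum(!keep))
}

#' Fit a T-augmented Gaussian mixture compartment model
#'
#' Fits one Gaussian component per compartment on its marker profiles
#' (empirical mean; covariance shrunk toward a scaled identity), plus a
#' single heavy-tailed outlier component: a multivariate t centered on
#' the global marker mean with scale `outlier_scale` times the pooled
#' covariance. Class prior weights are proportional to marker counts and
#' scaled by `1 - epsilon`; the outlier component receives prior
#' `epsilon`.
#'
#' @param X Marker profile matrix (markers x features); with R replicates
#'   of F fractions, features are the R concatenated length-F profile
#'   segments.
#' @param labels Compartment label per marker row.
#' @param lambda Shrinkage: ridge added to each class covariance equal to
#'   `lambda * tr(S)` (a fraction of the total variance) on the diagonal
#'   (default 0.01).
#' @param outlier_scale Scale multiplier for the outlier covariance
#'   (default 4).
#' @param epsilon Outlier prior mass (default 1e-6); 0 disables the
#'   outlier component.
#' @param outlier_df Degrees of freedom of the t-distributed outlier
#'   component (default 4).
#' @return Object of class `compartment_model`.
#' @seealso [allocate()], [expected_fdr()]
#' @export
fit_compartment_model <- function(X, labels, lambda = 0.01,
                                  outlier_scale = 4, epsilon = 1e-6,
                                  outlier_df = 4) {
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  if (anyNA(X)) stop("marker profiles must be complete (no missing values)")
  cls <- sort(unique(labels))
  d <- ncol(X)
  comp <- lapply(cls, function(c) {
    Xi <- X[labels == c, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- if (nrow(Xi) > 1L) stats::cov(Xi) else matrix(0, d, d)
    # ridge = lambda x total variance: marker counts per class are far
    # below the profile dimension, so the empirical covariance is rank
    # deficient and needs substantial diagonal mass
    ridge <- lambda * sum(diag(S))
    if (ridge <= 0) ridge <- 1e-8   # degenerate class: regularization floor
    S <- S + diag(ridge, d)
    R <- tryCatch(chol_pd(S), error = function(e)
      stop("singular covariance after regularization in class '", c, "'",
           call. = FALSE))
    list(mu = mu, sigma = S, chol = R, n = nrow(Xi))
  })
  names(comp) <- cls
  n_tot <- nrow(X)
  priors <- vapply(comp, function(c) c$n, numeric(1)) / n_tot * (1 - epsilon)
  pooled <- Reduce(`+`, lapply(comp, function(c) c$sigma * c$n)) / n_tot
  out_sigma <- outlier_scale * pooled
  structure(list(
    classes = cls, components = comp, priors = priors,
    outlier = list(mu = colMeans(X), sigma = out_sigma,
                   chol = chol_pd(out_sigma, "outlier scale"),
                   df = outlier_df, prior = epsilon),
    d = d, lambda = lambda, outlier_scale = outlier_scale,
    epsilon = epsilon
  ), class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat("T-augmented Gaussian mixture compartment model\n")
  cat(sprintf("  %d compartments, %d features, outlier prior %.3g (t, df %g)\n",
              length(x$classes), x$d, x$outlier$prior, x$outlier$df))
  counts <- vapply(x$components, function(c) c$n, numeric(1))
  print(data.frame(compartment = x$classes, markers = counts,
                   prior = round(x$priors, 4), row.names = NULL))
  invisible(x)
}

#' @export
summary.compartment_model <- function(object, ...) print(object, ...)

#' Allocate protein profiles to subcellular compartments
#'
#' Maximum-a-posteriori allocation under the fitted mixture: posterior
#' probability of each compartment (and of the outlier component) is
#' proportional to prior times component density, normalized so class
#' posteriors plus the outlier posterior sum to 1. A call is confident
#' when the top compartment posterior exceeds `threshold`.
#'
#' @param model A [fit_compartment_model()] object.
#' @param X Profile matrix (proteins x features) or a single profile
#'   vector; feature dimension must match the model.
#' @param threshold Confidence threshold on the top compartment posterior
#'   (default 0.95).
#' @return Data frame with one row per profile: `id`, `compartment`,
#'   `probability`, `outlier_prob`, `confident`; the full posterior
#'   matrix (classes + `outlier` column) is attached as attribute
#'   `"posterior"`.
#' @export
allocate <- function(model, X, threshold = 0.95) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$d)
    stop("profile has ", ncol(X), " features but model expects ", model$d)
  if (anyNA(X)) stop("profiles with missing values cannot be allocated")
  k <- length(model$classes)
  logp <- matrix(NA_real_, nrow(X), k + 1L,
                 dimnames = list(rownames(X), c(model$classes, "outlier")))
  for (i in seq_len(k)) {
    cm <- model$components[[i]]
    logp[, i] <- log(model$priors[i]) + log_dmvnorm_chol(X, cm$mu, cm$chol)
  }
  logp[, k + 1L] <- if (model$outlier$prior > 0) {
    log(model$outlier$prior) +
      log_dmvt_chol(X, model$outlier$mu, model$outlier$chol, model$outlier$df)
  } else -Inf
  post <- exp(logp - row_logsumexp(logp))
  top <- max.col(post[, seq_len(k), drop = FALSE], ties.method = "first")
  prob <- post[cbind(seq_len(nrow(X)), top)]
  data.frame(
    id = rownames(X) %||% as.character(seq_len(nrow(X))),
    compartment = model$classes[top],
    probability = prob,
    outlier_prob = post[, k + 1L],
    confident = prob > threshold,
    row.names = NULL
  ) -> out
  attr(out, "posterior") <- post
  out
}

#' @export
predict.compartment_model <- function(object, newdata, threshold = 0.95, ...) {
  allocate(object, newdata, threshold = threshold)
}

#' Expected false discovery rate of confident allocations
#'
#' Mean posterior error, `mean(1 - probability)`, over calls whose
#' probability exceeds the threshold.
#'
#' @param probability Posterior probabilities of the reported calls.
#' @param threshold Probability threshold (default 0.95).
#' @return Expected FDR, or `NA` when no call passes.
#' @export
#' @examples
#' expected_fdr(c(0.96, 0.98))  # 0.03
expected_fdr <- function(probability, threshold = 0.95) {
  passing <- probability[!is.na(probability) & probability > threshold]
  if (length(passing) == 0L) return(NA_real_)
  mean(1 - passing)
}
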