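#' Fit a Gaussian mixture to a Ks distribution on the log scale
#'
#' Values are filtered to \code{window}, log-transformed, and Gaussian
#' mixtures with 1..\code{max_components} components are fitted by EM
#' (k-means initialisation, \code{n_restarts} seeded restarts per component
#' count). The component count is chosen by the Bayesian information
#' criterion. Components are reported sorted by mean.
#'
#' @param ks_values numeric vector of Ks values; NAs are dropped.
#' @param max_components maximum number of mixture components (default 4).
#' @param window Ks values outside (window[1], window[2]) are excluded;
#'   default c(0.005, 5): the lower bound excludes allelic/tandem noise, the
#'   upper bound excludes saturated estimates.
#' @param n_restarts EM restarts per component count (default 10).
#' @param min_values refuse to fit on fewer values (default 50; small samples
#'   give unstable mixtures).
#' @param seed integer seed controlling initialisation (default 1).
#' @return An object of class \code{ks_peak_model}: data.frame
#'   \code{components} (weight, mu, sigma on log-Ks, and \code{peak_ks} =
#'   exp(mu)), \code{n_components}, \code{bic} for each candidate count,
#'   \code{loglik}, and \code{n} used.
#' @export
fit_peaks <- function(ks_values, max_components = 4L,
                      window = c(0.005, 5), n_restarts = 10L,
                      min_values = 50L, seed = 1L) {
  x <- ks_values[!is.na(ks_values)]
  x <- x[x > window[1L] & x < window[2L]]
  if (length(x) < min_values)
    stop("refusing to fit a mixture on ", length(x), " values (< ",
         min_values, "): unstable fit")
  lx <- log(x)
  if (stats::sd(lx) < 1e-8)
    stop("refusing to fit: degenerate (near-constant) Ks values")
  n <- length(lx)
  fits <- vector("list", max_components)
  bics <- rep(NA_real_, max_components)
  for (k in seq_len(max_components)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- em_init(lx, k, seed = seed * 1000L + k * 100L + r)
      f <- em_gmm(lx, init$w, init$mu, init$sigma)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    fits[[k]] <- best
    bics[k] <- -2 * best$loglik + (3 * k - 1) * log(n)
  }
  k_sel <- which.min(bics)
  f <- fits[[k_sel]]
  ord <- order(f$mu)
  comps <- data.frame(weight = f$w[ord], mu = f$mu[ord],
                      sigma = f$sigma[ord], peak_ks = exp(f$mu[ord]))
  structure(list(components = comps, n_components = k_sel,
                 bic = bics, loglik = f$loglik, n = n),
            class = "ks_peak_model")
}

em_init <- function(lx, k, seed) {
  set.seed(seed %% .Machine$integer.max)
  if (k == 1L) {
    return(list(w = 1, mu = mean(lx), sigma = stats::sd(lx)))
  }
  km <- suppressWarnings(stats::kmeans(lx, centers = k, nstart = 1L,
                                       iter.max = 50L))
  mu <- as.numeric(km$centers)
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / length(lx)
  sigma <- vapply(seq_len(k), function(j) {
    v <- lx[km$cluster == j]
    s <- if (length(v) > 1L) stats::sd(v) else stats::sd(lx) / k
    max(s, 1e-3)
  }, numeric(1L))
  w <- pmax(w, 1e-6)
  list(w = w / sum(w), mu = mu, sigma = sigma)
}

# 1-D Gaussian mixture EM; log-likelihood is non-decreasing by construction.
em_gmm <- function(lx, w, mu, sigma, max_iter = 500L, tol = 1e-8) {
  n <- length(lx)
  k <- length(w)
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(lx, mu[j], sigma[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < 1e-300] <- 1e-300
    new_ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * lx) / nk
    sigma <- sqrt(colSums(resp * (lx - rep(mu, each = n))^2) / nk)
    sigma <- pmax(sigma, 1e-4)
    if (is.finite(loglik) && new_ll - loglik < tol) {
      loglik <- new_ll
      break
    }
    loglik <- new_ll
  }
  list(w = w, mu = mu, sigma = sigma, loglik = loglik, iterations = iter)
}

#' @export
print.ks_peak_model <- function(x, ...) {
  cat(sprintf("Ks mixture: %d component(s) over %d values (BIC-selected)\n",
              x$n_components, x$n))
  comps <- x$components
  for (i in seq_len(nrow(comps)))
    cat(sprintf("  peak %d: Ks=%.3f (weight %.2f, sigma %.2f on log scale)\n",
                i, comps$peak_ks[i], comps$weight[i], comps$sigma[i]))
  invisible(x)
}

#' Designate the gamma-event component of a peak model
#'
#' Picks the component whose \code{peak_ks} is nearest \code{prior} (default
#' 1.2, the expected location of the core-eudicot triplication peak). If two
#' components fall within \code{ambiguity} relative distance of each other
#' around the prior, an explicit choice is demanded.
#'
#' @param model a \code{ks_peak_model}.
#' @param prior prior gamma peak location on the Ks scale (default 1.2).
#' @param ambiguity relative closeness below which two candidates are
#'   ambiguous (default 0.15).
#' @return the designated component's \code{peak_ks}.
#' @export
gamma_component <- function(model, prior = 1.2, ambiguity = 0.15) {
  pk <- model$components$peak_ks
  d <- abs(log(pk) - log(prior))
  ord <- order(d)
  if (length(pk) > 1L) {
    p1 <- pk[ord[1L]]
    p2 <- pk[ord[2L]]
    if (abs(p1 - p2) / max(p1, p2) < ambiguity)
      stop("ambiguous gamma component: peaks ", signif(p1, 3), " and ",
           signif(p2, 3), " are within ", ambiguity * 100,
           "% of each other; choose explicitly")
  }
  pk[ord[1L]]
}

#' Correct Ks values for lineage-specific evolutionary rate
#'
#' A shared event (the gamma triplication) must sit at the same Ks in every
#' lineage; rate variation displaces it. The correction is a single
#' multiplicative factor per species,
#' f = gamma_peak(reference) / gamma_peak(species), applied to every Ks
#' value, so the corrected gamma peak of the species coincides with the
#' reference by construction.
#'
#' @param ks_values numeric Ks values of the species.
#' @param peak_species the species' gamma peak Ks.
#' @param peak_reference the reference (e.g. grape) gamma peak Ks.
#' @param species,reference labels carried in the result.
#' @return list with \code{corrected} values, \code{factor}, \code{species},
#'   \code{reference}.
#' @export
correct_rates <- function(ks_values, peak_species, peak_reference,
                          species = "species", reference = "reference") {
  if (!is.finite(peak_species) || peak_species <= 0)
    stop("species gamma peak must be > 0")
  if (!is.finite(peak_reference) || peak_reference <= 0)
    stop("reference gamma peak must be > 0")
  f <- peak_reference / peak_species
  list(corrected = ks_values * f, factor = f,
       species = species, reference = reference)
}

#' Date an event from its Ks peak
#'
#' T = Ks / (2 r) with r the synonymous substitution rate per site per year;
#' the result is reported in millions of years (Mya).
#'
#' @param gamma_peak_ks Ks location of the event peak.
#' @param rate synonymous substitution rate r, per site per year (> 0).
#' @return time in Mya.
#' @examples
#' date_event(1.22, 5e-9)  # 122 Mya
#' @export
date_event <- function(gamma_peak_ks, rate) {
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  gamma_peak_ks / (2 * rate) / 1e6
}
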