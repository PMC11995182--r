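#' @title Codon sequence divergence simulation
#' @name seqsim
#' @description A K80-style nucleotide substitution process with stop-codon
#'   rejection, calibrated so that the NG86 Ks of a simulated pair matches a
#'   target on average. Only synonymous-distance recovery is needed by the
#'   pipeline tests, so a full codon model is deliberately out of scope: the
#'   NG86 estimator itself defines the truth scale.
NULL

BASES <- c("A", "C", "G", "T")
TS_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")

#' Generate a random CDS with no internal stop codons
#'
#' @param n_codons number of codons (first codon is ATG).
#' @param seed optional integer seed.
#' @return a CDS string of length 3 * n_codons.
#' @export
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- ng86_tables()
  ok <- tab$codons[tab$aa != "*"]
  paste0(c("ATG", sample(ok, n_codons - 1L, replace = TRUE)), collapse = "")
}

# Calibration tables: ancestor codon composition plus the codon-level jump
# kernel of the substitution process. An event picks one of the three
# positions uniformly, draws the alternative base with weights
# (kappa, 1, 1)/(kappa + 2) (transition vs the two transversions), and is
# discarded when it would create a stop codon (a self-loop) -- exactly the
# process apply_events() simulates.
site_pair_tables <- function(seq, kappa) {
  tab <- ng86_tables()
  cods <- split_codons(seq)
  codons <- tab$codons
  n <- length(codons)
  J <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    ci <- strsplit(codons[i], "")[[1L]]
    for (pos in 1:3) {
      b <- ci[pos]
      for (u in setdiff(BASES, b)) {
        w <- if (u == TS_PARTNER[[b]]) kappa else 1
        cj <- ci
        cj[pos] <- u
        target <- paste0(cj, collapse = "")
        p <- (1 / 3) * w / (kappa + 2)
        if (tab$aa[[target]] == "*") {
          J[i, i] <- J[i, i] + p  # discarded event
        } else {
          J[i, match(target, codons)] <- p
        }
      }
    }
    J[i, i] <- J[i, i] + 1 - sum(J[i, ])
  }
  list(anc_idx = match(cods, codons), J = J,
       syn_sites = unname(tab$syn_sites[codons]),
       SdM = tab$SdM, L = nchar(seq))
}

# Codon transition matrix after Poisson(3 m) events per codon with jump
# kernel J, by uniformization: T = sum_k dpois(k, 3m) J^k.
codon_transition <- function(m, J) {
  r <- 3 * m
  kmax <- max(5L, stats::qpois(1 - 1e-12, r))
  Tm <- diag(nrow(J)) * stats::dpois(0L, r)
  Jk <- diag(nrow(J))
  for (k in seq_len(kmax)) {
    Jk <- Jk %*% J
    Tm <- Tm + stats::dpois(k, r) * Jk
  }
  Tm
}

# Predicted NG86 Ks for a pair separated by total per-site event count m:
# the two tip codons are independent draws from the exact codon-level chain
# run for m/2 events per site on each branch; expected S and Sd then follow
# from the NG86 counting tables.
predict_ks <- function(m, kappa, tables) {
  Th <- codon_transition(m / 2, tables$J)
  P <- Th[tables$anc_idx, , drop = FALSE]
  e_S <- sum(P %*% tables$syn_sites)
  e_Sd <- sum(rowSums((P %*% tables$SdM) * P))
  pS <- e_Sd / e_S
  if (pS >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * pS / 3)
}

# Solve for the total per-site event count whose predicted NG86 Ks equals
# the target.
calibrate_events <- function(seq, target_ks, kappa) {
  if (target_ks == 0) return(0)
  tables <- site_pair_tables(seq, kappa)
  upper <- 12
  kmax <- predict_ks(upper, kappa, tables)
  if (!is.finite(kmax) ) kmax <- Inf
  if (is.finite(kmax) && target_ks >= kmax)
    stop("target Ks ", target_ks, " unreachable before saturation; ",
         "use a longer sequence or a smaller target")
  f <- function(m) predict_ks(m, kappa, tables) - target_ks
  if (!is.finite(predict_ks(upper, kappa, tables))) {
    # shrink upper below the saturation point
    while (!is.finite(predict_ks(upper, kappa, tables)) && upper > 1e-3)
      upper <- upper * 0.9
    if (f(upper) < 0)
      stop("target Ks ", target_ks, " unreachable before saturation; ",
           "use a longer sequence or a smaller target")
  }
  stats::uniroot(f, c(1e-9, upper), tol = 1e-9)$root
}

# Apply n K80 jump events to a base vector; an event that would create a
# stop codon is discarded (consumed without effect), matching the
# uniformized codon chain used for calibration. Returns list(seq,
# syn_events).
apply_events <- function(bvec, n_events, kappa) {
  tab <- ng86_tables()
  L <- length(bvec)
  syn_events <- 0L
  p_ts <- kappa / (kappa + 2)
  if (n_events == 0L) return(list(seq = bvec, syn_events = 0L))
  sites <- sample.int(L, n_events, replace = TRUE)
  is_ts <- stats::runif(n_events) < p_ts
  tv_pick <- sample.int(2L, n_events, replace = TRUE)
  for (i in seq_len(n_events)) {
    site <- sites[i]
    b <- bvec[site]
    alt <- if (is_ts[i]) {
      TS_PARTNER[[b]]
    } else {
      setdiff(BASES, c(b, TS_PARTNER[[b]]))[tv_pick[i]]
    }
    c0 <- site - (site - 1L) %% 3L
    codon <- bvec[c0:(c0 + 2L)]
    old_codon <- paste0(codon, collapse = "")
    codon[site - c0 + 1L] <- alt
    new_codon <- paste0(codon, collapse = "")
    if (tab$aa[[new_codon]] == "*") next  # discarded event
    if (tab$aa[[new_codon]] == tab$aa[[old_codon]])
      syn_events <- syn_events + 1L
    bvec[site] <- alt
  }
  list(seq = bvec, syn_events = syn_events)
}

#' Evolve a CDS along one branch to a target synonymous distance
#'
#' @param cds ancestral CDS (no internal stops).
#' @param branch_ks target synonymous distance of the branch (NG86 scale):
#'   a pair (ancestor, evolved copy) has expected NG86 Ks equal to
#'   \code{branch_ks}.
#' @param kappa transition/transversion ratio (default 2).
#' @param seed optional integer seed.
#' @return list with \code{cds} (evolved sequence), \code{n_events},
#'   \code{syn_events}.
#' @export
mutate_cds <- function(cds, branch_ks, kappa = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cds <- toupper(cds)
  if (branch_ks == 0)
    return(list(cds = cds, n_events = 0L, syn_events = 0L))
  m <- calibrate_events(cds, branch_ks, kappa)
  L <- nchar(cds)
  n_events <- stats::rpois(1L, m * L)
  res <- apply_events(strsplit(cds, "")[[1L]], n_events, kappa)
  list(cds = paste0(res$seq, collapse = ""), n_events = n_events,
       syn_events = res$syn_events)
}

#' Simulate a pair of coding sequences at a target NG86 Ks
#'
#' Generates a random ancestral CDS and evolves two copies, each over half
#' the target distance, under a K80-style jump process with stop-codon
#' rejection. The Poisson event count is calibrated semi-analytically so
#' that the NG86 Ks of the pair matches \code{target_ks} on average
#' (within ~5 percent for n_codons >= 300).
#'
#' @param n_codons number of codons (>= 50).
#' @param target_ks target synonymous distance (< 3, below saturation).
#' @param kappa transition/transversion ratio (default 2).
#' @param seed optional integer seed.
#' @return list with \code{cds_a}, \code{cds_b}, \code{ancestor}, and
#'   \code{true_ks}: realized synonymous substitution events per ancestral
#'   synonymous site.
#' @export
evolve_cds_pair <- function(n_codons, target_ks, kappa = 2, seed = NULL) {
  stopifnot(n_codons >= 50L)
  if (target_ks >= 3)
    stop("target_ks must be < 3 (saturation)")
  if (!is.null(seed)) set.seed(seed)
  anc <- random_cds(n_codons)
  if (target_ks == 0)
    return(list(cds_a = anc, cds_b = anc, ancestor = anc, true_ks = 0))
  m <- calibrate_events(anc, target_ks, kappa)
  L <- nchar(anc)
  S_anc <- sum(ng86_tables()$syn_sites[split_codons(anc)])
  evolve_one <- function() {
    n_events <- stats::rpois(1L, m * L / 2)
    apply_events(strsplit(anc, "")[[1L]], n_events, kappa)
  }
  a <- evolve_one()
  b <- evolve_one()
  list(cds_a = paste0(a$seq, collapse = ""),
       cds_b = paste0(b$seq, collapse = ""),
       ancestor = anc,
       true_ks = (a$syn_events + b$syn_events) / S_anc)
}
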