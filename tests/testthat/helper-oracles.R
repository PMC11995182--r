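# Independent oracles, implemented along different code paths than the
# package: per-codon enumeration for NG86, exhaustive DFS for chaining,
# classic DP for protein alignment.

# --- NG86 by direct enumeration ---------------------------------------

oracle_codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- oracle_codon_aa(codon)
  total <- 0
  for (pos in 1:3) {
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (oracle_codon_aa(alt) == aa0) total <- total + 1 / 3
    }
  }
  total
}

# all minimal pathways by depth-first search over differing positions;
# pathways through a stop codon are skipped unless none survives
oracle_codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, sd, nd, valid) {
    dpos <- which(strsplit(cur, "")[[1L]] != strsplit(c2, "")[[1L]])
    if (!length(dpos)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd, valid)
      return(invisible())
    }
    for (p in dpos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      syn <- oracle_codon_aa(cur) == oracle_codon_aa(nxt)
      v <- valid && (oracle_codon_aa(nxt) != "*" || nxt == c2)
      walk(nxt, sd + as.numeric(syn), nd + as.numeric(!syn), v)
    }
  }
  walk(c1, 0, 0, TRUE)
  mat <- do.call(rbind, paths)
  use <- mat[, 3L] == 1
  if (!any(use)) use <- rep(TRUE, nrow(mat))
  c(sd = mean(mat[use, 1L]), nd = mean(mat[use, 2L]))
}

oracle_ng86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  S <- (sum(vapply(ca, oracle_syn_sites, 1)) +
          sum(vapply(cb, oracle_syn_sites, 1))) / 2
  d <- vapply(seq_along(ca), function(i) oracle_codon_diffs(ca[i], cb[i]),
              numeric(2L))
  list(S = S, N = 3 * length(ca) - S, Sd = sum(d["sd", ]),
       Nd = sum(d["nd", ]))
}

random_codon_seq <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T"))[, 3:1], 1L, paste0,
                  collapse = "")
  ok <- codons[!Biostrings::GENETIC_CODE[codons] %in% "*"]
  paste0(sample(ok, n_codons, replace = TRUE), collapse = "")
}

# --- exhaustive chain enumeration -------------------------------------

# maximum chain score over all gap-feasible strictly monotonic chains,
# for one orientation (pass rb or -rb); plain DFS, no DP
oracle_top_chain_score <- function(ra, rb, sc, max_gap, gap_penalty) {
  n <- length(ra)
  best <- -Inf
  succ <- lapply(seq_len(n), function(i) {
    which(ra > ra[i] & rb > rb[i] &
            ra - ra[i] - 1L <= max_gap & rb - rb[i] - 1L <= max_gap)
  })
  dfs <- function(i, score) {
    best <<- max(best, score)
    for (j in succ[[i]]) {
      dfs(j, score + sc[j] -
            gap_penalty * ((ra[j] - ra[i] - 1L) + (rb[j] - rb[i] - 1L)))
    }
  }
  for (i in seq_len(n)) dfs(i, sc[i])
  best
}

oracle_best_over_orientations <- function(anchors, max_gap, gap_penalty) {
  best <- -Inf
  for (key in unique(paste(anchors$chr_a, anchors$chr_b))) {
    sub <- anchors[paste(anchors$chr_a, anchors$chr_b) == key, ]
    for (sgn in c(1L, -1L)) {
      best <- max(best, oracle_top_chain_score(sub$rank_a, sgn * sub$rank_b,
                                               sub$score, max_gap,
                                               gap_penalty))
    }
  }
  best
}

# --- Needleman-Wunsch with linear gaps --------------------------------

oracle_nw_score <- function(a, b, match, mismatch, gap) {
  a <- strsplit(a, "")[[1L]]
  b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  dp <- matrix(0, n + 1L, m + 1L)
  dp[, 1L] <- seq(0L, n) * -gap
  dp[1L, ] <- seq(0L, m) * -gap
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      dp[i + 1L, j + 1L] <- max(dp[i, j] + s, dp[i, j + 1L] - gap,
                                dp[i + 1L, j] - gap)
    }
  }
  dp[n + 1L, m + 1L]
}
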