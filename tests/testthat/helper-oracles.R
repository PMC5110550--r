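# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# --- optimal one-to-one assignment between two call sets ------------------
# Enumerates candidate pairs (same chrom/family, distance <= window), splits
# them into connected components via shared calls, and solves each component
# exhaustively for the assignment maximizing matched-pair count (ties: the
# minimum total distance). Feasible for the small, sparse inputs used in
# tests.
oracle_assignment <- function(a, b, window) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$family[i] == b$family[j] &&
          abs(a$pos[i] - b$pos[j]) <= window) {
        pairs[[length(pairs) + 1]] <- c(i, j, abs(a$pos[i] - b$pos[j]))
      }
    }
  }
  if (length(pairs) == 0) return(list(count = 0L, dist = 0))
  pm <- do.call(rbind, pairs)

  # connected components over shared A/B indices
  comp <- seq_len(nrow(pm))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(pm))) {
      for (j in seq_len(nrow(pm))) {
        if (comp[i] != comp[j] &&
            (pm[i, 1] == pm[j, 1] || pm[i, 2] == pm[j, 2])) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  best_total <- 0L
  best_dist <- 0
  for (cc in unique(comp)) {
    sub <- pm[comp == cc, , drop = FALSE]
    best <- c(0L, Inf)
    solve <- function(k, used_a, used_b, cnt, dst) {
      if (k > nrow(sub)) {
        if (cnt > best[1] || (cnt == best[1] && dst < best[2])) {
          best <<- c(cnt, dst)
        }
        return(invisible())
      }
      solve(k + 1, used_a, used_b, cnt, dst)
      if (!(sub[k, 1] %in% used_a) && !(sub[k, 2] %in% used_b)) {
        solve(k + 1, c(used_a, sub[k, 1]), c(used_b, sub[k, 2]),
          cnt + 1L, dst + sub[k, 3])
      }
    }
    solve(1L, integer(), integer(), 0L, 0)
    best_total <- best_total + best[1]
    best_dist <- best_dist + best[2]
  }
  list(count = best_total, dist = best_dist)
}

# --- two-sample KS statistic: exhaustive max ECDF gap ----------------------
oracle_ks_stat <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(vapply(grid, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# --- Fisher exact two-sided p by choose()-based enumeration ----------------
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# --- genomic context by direct scan ---------------------------------------
oracle_context <- function(chrom, pos, features) {
  p0 <- pos - 1
  ex <- features$exons
  for (i in seq_len(nrow(ex))) {
    if (ex$chrom[i] == chrom && p0 >= ex$start[i] && p0 < ex$end[i]) {
      return("exonic")
    }
  }
  en <- features$enhancers
  for (i in seq_len(nrow(en))) {
    if (en$chrom[i] == chrom && p0 >= en$start[i] && p0 < en$end[i]) {
      return("regulatory")
    }
  }
  g <- features$genes
  for (i in seq_len(nrow(g))) {
    if (g$chrom[i] == chrom && p0 >= g$tx_start[i] && p0 < g$tx_end[i]) {
      return("intronic")
    }
  }
  "intergenic"
}

# --- EM objective: coarse-to-fine grid search over the simplex -------------
# Log-likelihood of proportions p for a list of candidate index sets.
oracle_em_loglik <- function(p, cand_sets) {
  sum(vapply(cand_sets, function(s) log(sum(p[s])), numeric(1)))
}

oracle_em_grid <- function(reads, loci) {
  cand_sets <- split(match(reads$locus_id, loci), reads$read_id)
  k <- length(loci)
  eval_grid <- function(pts) {
    ll <- apply(pts, 1, oracle_em_loglik, cand_sets = cand_sets)
    pts[which.max(ll), ]
  }
  axis <- function(step, c_i, radius) {
    if (is.null(radius)) seq(0, 1, by = step) else
      seq(max(0, c_i - radius), min(1, c_i + radius), by = step)
  }
  simplex_grid <- function(step, centre = NULL, radius = NULL) {
    if (k == 2) {
      s <- axis(step, centre[1], radius)
      cbind(s, 1 - s)
    } else {
      g <- expand.grid(p1 = axis(step, centre[1], radius),
        p2 = axis(step, centre[2], radius))
      g <- g[g$p1 + g$p2 <= 1 + 1e-12, ]
      cbind(g$p1, g$p2, pmax(0, 1 - g$p1 - g$p2))
    }
  }
  pts <- eval_grid(simplex_grid(if (k == 2) 1e-3 else 5e-3))
  pts <- eval_grid(simplex_grid(if (k == 2) 1e-5 else 2e-4,
    centre = pts, radius = if (k == 2) 2e-3 else 1e-2))
  if (k == 3) {
    pts <- eval_grid(simplex_grid(1e-5, centre = pts, radius = 5e-4))
  }
  pts
}

# --- shared small fixtures -------------------------------------------------
make_calls <- function(pos, family = "L1", chrom = "chr1",
                       support = 10L, caller = "a", sample = "P01.tumor") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    family = rep_len(family, length(pos)),
    support_reads = as.integer(rep_len(support, length(pos))),
    caller_id = caller, sample_id = sample,
    tissue = sub("^.*\\.", "", sample)
  )
}

# A random well-spaced two-caller scenario honouring the generator contract
# (truth loci >= 500 bp apart, jitter <= 100 bp, FPs >= 500 bp from truth).
random_spaced_scenario <- function(n_truth, n_fp_a = 2, n_fp_b = 2,
                                   families = c("Alu", "L1", "SVA")) {
  slots <- sample(seq(1000, 5e6, by = 600), n_truth + n_fp_a + n_fp_b)
  truth_pos <- slots[seq_len(n_truth)]
  fam <- sample(families, n_truth, replace = TRUE)
  jit <- function(p) pmax(1, p + sample(-100:100, length(p), replace = TRUE))
  miss_a <- runif(n_truth) < 0.15
  miss_b <- runif(n_truth) < 0.15
  a <- make_calls(jit(truth_pos[!miss_a]), family = fam[!miss_a],
    caller = "a")
  b <- make_calls(jit(truth_pos[!miss_b]), family = fam[!miss_b],
    caller = "b")
  fp_a <- slots[n_truth + seq_len(n_fp_a)]
  fp_b <- slots[n_truth + n_fp_a + seq_len(n_fp_b)]
  a <- rbind(a, make_calls(fp_a, family = sample(families, n_fp_a, TRUE),
    caller = "a"))
  b <- rbind(b, make_calls(fp_b, family = sample(families, n_fp_b, TRUE),
    caller = "b"))
  list(a = a[sample(nrow(a)), ], b = b[sample(nrow(b)), ])
}
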