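# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code paths they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive affine-gap global alignment score by full Gotoh DP.
# Convention: a gap of length k costs open + (k - 1) * extend.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = 4, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap consuming a
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap consuming b
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - (i - 1) * extend
  for (j in seq_len(m)) Y[1, j + 1] <- -open - (j - 1) * extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open, Y[i, j + 1] - open,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open, X[i + 1, j] - open,
                             Y[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# quadratic-time Benjamini-Hochberg step-up reference
oracle_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  for (i in ok) {
    rank_i <- sum(p[ok] <= p[i])
    cands <- vapply(ok, function(j) {
      if (p[j] >= p[i]) p[j] * m / sum(p[ok] <= p[j]) else Inf
    }, numeric(1))
    out[i] <- min(1, min(cands))
  }
  out
}

# independent unit-pairing oracle: adjacency-list graph built from scratch,
# components by depth-first search, eligibility by direct scan of each
# component's sites against the full site-pair list
oracle_pair_units <- function(units_a, units_b, site_pairs) {
  ua <- sort(unique(units_a$unit_id)); ub <- sort(unique(units_b$unit_id))
  node <- c(paste0("A", ua), paste0("B", ub))
  adj <- setNames(vector("list", length(node)), node)
  unit_at <- function(units, pos) {
    h <- units$unit_id[units$pos == pos]
    if (length(h)) h else NA_integer_
  }
  for (k in seq_len(nrow(site_pairs))) {
    x <- unit_at(units_a, site_pairs$pos_a[k])
    y <- unit_at(units_b, site_pairs$pos_b[k])
    if (!is.na(x) && !is.na(y)) {
      nx <- paste0("A", x); ny <- paste0("B", y)
      adj[[nx]] <- union(adj[[nx]], ny)
      adj[[ny]] <- union(adj[[ny]], nx)
    }
  }
  seen <- character()
  comps <- list()
  for (v in node) {
    if (v %in% seen || length(adj[[v]]) == 0) next
    stack <- v; comp <- character()
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      stack <- c(stack, setdiff(adj[[u]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  # eligibility scan
  keep <- list(); rejected <- list()
  for (comp in comps) {
    mem_a <- as.integer(sub("^A", "", comp[startsWith(comp, "A")]))
    mem_b <- as.integer(sub("^B", "", comp[startsWith(comp, "B")]))
    sa <- units_a$pos[units_a$unit_id %in% mem_a]
    sb <- units_b$pos[units_b$unit_id %in% mem_b]
    bad <- FALSE
    for (k in seq_len(nrow(site_pairs))) {
      pa <- site_pairs$pos_a[k]; pb <- site_pairs$pos_b[k]
      if (!(pa %in% sa) && !(pb %in% sb)) next
      x <- unit_at(units_a, pa); y <- unit_at(units_b, pb)
      within <- !is.na(x) && !is.na(y) && x %in% mem_a && y %in% mem_b
      if (!within) { bad <- TRUE; break }
    }
    if (bad) rejected[[length(rejected) + 1L]] <- list(a = mem_a, b = mem_b)
    else keep[[length(keep) + 1L]] <- list(a = mem_a, b = mem_b)
  }
  canon <- function(l) {
    if (!length(l)) return(character())
    sort(vapply(l, function(g)
      paste0("A:", paste(sort(g$a), collapse = ","),
             "|B:", paste(sort(g$b), collapse = ",")), character(1)))
  }
  list(paired = canon(keep), rejected = canon(rejected))
}

# canonical form of pair_cpg_units() groups for comparison with the oracle
canon_paired <- function(pu) {
  g <- pu$groups
  paired <- sort(vapply(seq_len(nrow(g)), function(i)
    paste0("A:", paste(sort(g$units_a[[i]]), collapse = ","),
           "|B:", paste(sort(g$units_b[[i]]), collapse = ",")), character(1)))
  ex <- pu$excluded
  rej <- ex[ex$reason %in% c("conflicting_partner", "ineligible_counterpart"), ]
  list(paired = paired, excluded = ex)
}

# random small pairing instance: two species' unit maps over a shared
# ancestral site lattice with per-species loss and optional unmeasured units
random_pairing_instance <- function(max_units = 8) {
  repeat {
    inst <- random_pairing_instance_once()
    if (length(unique(inst$units_a$unit_id)) <= max_units &&
        length(unique(inst$units_b$unit_id)) <= max_units) {
      return(inst)
    }
  }
}

random_pairing_instance_once <- function() {
  n_sites <- sample(3:20, 1)
  pos <- sort(sample(0:200, n_sites))
  keep_a <- runif(n_sites) > 0.25
  keep_b <- runif(n_sites) > 0.25
  gap <- sample(c(8, 15, 25), 1)
  units_a <- group_cpg_units(pos[keep_a], gap)
  units_b <- group_cpg_units(pos[keep_b], gap)
  # drop some units from measurement (EpiTYPER-style unreliable units)
  if (nrow(units_a) > 0 && runif(1) < 0.3) {
    drop <- sample(unique(units_a$unit_id), 1)
    units_a <- units_a[units_a$unit_id != drop, ]
  }
  if (nrow(units_b) > 0 && runif(1) < 0.3) {
    drop <- sample(unique(units_b$unit_id), 1)
    units_b <- units_b[units_b$unit_id != drop, ]
  }
  both <- keep_a & keep_b
  list(units_a = units_a, units_b = units_b,
       site_pairs = tibble::tibble(pos_a = pos[both], pos_b = pos[both]))
}
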