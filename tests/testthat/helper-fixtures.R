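# Hand-built and generated fixtures plus independent oracles used
# across the suite. Oracles deliberately re-derive results by brute
# force so they stay independent of the package code paths they check.

tiny_clone_table <- function() {
  tibble::tibble(
    clone_id = c("c1", "c2", "c3"),
    donor_id = c("D01", "D01", "D02"),
    subset = c("HSC", "CMP", "CDP"),
    culture = "MPFSG",
    division = c(0L, NA, NA),
    G = c(100L, 40L, 2L), M = c(50L, 40L, 0L), L = c(0L, 40L, 0L),
    DC1 = c(0L, 40L, 0L), DC2 = c(0L, 40L, 0L), pDC = c(0L, 40L, 0L)
  )
}

small_params <- function(...) {
  defaults <- list(
    n_clones = c(HSC = 60, CMP = 60, MDP = 40),
    unproductive_fraction = c(HSC = 0.3, CMP = 0.3, MDP = 0.3),
    n_donors = 4, seed = 42
  )
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

# naive O(N^3) complete-linkage agglomerator: returns sorted merge heights
naive_complete_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  active <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (j <= i) next
        h <- max(d[active[[i]], active[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(active[[best[2]]], active[[best[3]]])
    active <- active[-c(best[2], best[3])]
    active[[length(active) + 1]] <- merged
  }
  sort(heights)
}

# enumerate all 2^(N-1) subtree flips of an hclust tree; return the best
# adjacent-similarity objective and every order achieving it
brute_force_olo <- function(tree, S) {
  orders_of <- function(id) {
    if (id < 0) return(list(-id))
    left <- orders_of(tree$merge[id, 1])
    right <- orders_of(tree$merge[id, 2])
    out <- list()
    for (l in left) for (r in right) {
      out[[length(out) + 1]] <- c(l, r)
      out[[length(out) + 1]] <- c(r, l)
    }
    out
  }
  all_orders <- orders_of(nrow(tree$merge))
  obj <- vapply(all_orders, function(o) {
    sum(S[cbind(o[-length(o)], o[-1])])
  }, numeric(1))
  list(best = max(obj),
       orders = all_orders[obj == max(obj)])
}

# plain double-loop distances of every point to each backbone
brute_force_track_distances <- function(coords, members) {
  out <- matrix(Inf, nrow(coords), length(members))
  for (i in seq_len(nrow(coords))) {
    for (k in seq_along(members)) {
      if (length(members[[k]]) == 0) next
      best <- Inf
      for (j in members[[k]]) {
        dd <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        if (dd < best) best <- dd
      }
      out[i, k] <- best
    }
  }
  out
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# leaf sets of every internal node of an hclust tree
hclust_leaf_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (v in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[v, ]
    sets[[v]] <- c(
      if (kids[1] < 0) -kids[1] else sets[[kids[1]]],
      if (kids[2] < 0) -kids[2] else sets[[kids[2]]]
    )
  }
  sets
}
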