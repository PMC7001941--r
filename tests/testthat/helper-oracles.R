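# Independent oracles used across the suite: brute-force geometry, graph
# search, the general coagulation double sum, and a Gillespie stochastic
# simulator for monomer-only kinetics.  All deliberately naive.

# shortest displacement by explicit search over the 9 periodic images
brute_min_image <- function(p, q, L) {
  best <- NULL; bestn <- Inf
  for (ox in -1:1) for (oy in -1:1) {
    v <- q + c(ox, oy) * L - p
    if (sum(v^2) < bestn) { bestn <- sum(v^2); best <- v }
  }
  best
}

# all-pairs contact scan
brute_pairs <- function(pos, contact, L) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    v <- brute_min_image(pos[i, ], pos[j, ], L)
    if (sqrt(sum(v^2)) <= contact) out <- rbind(out, c(i, j))
  }
  out
}

# component count via breadth-first search
bfs_component_count <- function(n, pairs) {
  adj <- vector("list", n)
  if (!is.null(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); ncomp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  ncomp
}

# general coagulation right-hand side, Smoluchowski gain/loss double sum,
# evaluated term by term for an arbitrary kernel matrix
brute_coagulation_rhs <- function(spectrum, Kmat) {
  kmax <- length(spectrum)
  d <- numeric(kmax)
  for (k in seq_len(kmax)) {
    gain <- 0
    if (k >= 2) for (i in seq_len(k - 1))
      gain <- gain + Kmat[i, k - i] * spectrum[i] * spectrum[k - i]
    loss <- sum(Kmat[k, ] * spectrum) * spectrum[k]
    d[k] <- 0.5 * gain - loss
  }
  d
}

# Exact stochastic simulation of monomer-only coagulation.  Under that
# kernel the process is Markov in (N1, N): every event removes one cluster,
# a monomer-monomer event removes two monomers, a monomer-cluster event one.
# Returns a reps x length(times) matrix of total counts.
gillespie_monomer_totals <- function(N0, K1, times, reps) {
  n_events <- N0 - 1L
  N1 <- rep(N0, reps); N <- rep(N0, reps)
  tmat <- matrix(Inf, n_events, reps)
  tcur <- numeric(reps)
  for (e in seq_len(n_events)) {
    rate <- K1 * (N1 * (N1 - 1) / 2 + N1 * (N - N1))
    active <- rate > 0
    dt <- rep(Inf, reps)
    dt[active] <- rexp(sum(active), rate[active])
    tcur <- tcur + dt
    tmat[e, ] <- tcur
    p_mm <- ifelse(N > 1, (N1 - 1) / (2 * N - N1 - 1), 0)
    mm <- runif(reps) < p_mm
    N1 <- N1 - ifelse(active, ifelse(mm, 2L, 1L), 0L)
    N <- N - ifelse(active, 1L, 0L)
  }
  vapply(times, function(tau) N0 - colSums(tmat <= tau), numeric(reps))
}

# small fast configuration for engine tests: low cell count, small box
test_config <- function(n_initial = 60L, box_side = 200, step_length = "6 px",
                        kappa = 0, alpha_max = 0.7, compaction = TRUE,
                        flux = flux_spec(FALSE), n_iterations = 50L, ...) {
  abm_config(n_initial = n_initial, cell_diameter = 13.2,
             step_length = step_length, proliferation_rate = kappa,
             alpha_max = alpha_max, compaction = compaction, flux = flux,
             box = box_spec(box_side), n_iterations = n_iterations, ...)
}
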