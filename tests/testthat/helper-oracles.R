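# Independent oracles and small fixture builders used across the suite.

# O(N^2) minimum-image pair enumeration, independent of the cell-list code
brute_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  out <- list()
  for (i in seq_len(n - 1)) {
    d <- t(pos[i, ] - t(pos[(i + 1):n, , drop = FALSE]))
    B <- matrix(box, nrow(d), 3, byrow = TRUE)
    d <- d - B * round(d / B)
    r <- sqrt(rowSums(d^2))
    sel <- r < cutoff & r > 0
    if (any(sel))
      out[[length(out) + 1]] <- cbind(i, ((i + 1):n)[sel], r[sel])
  }
  if (length(out) == 0) return(matrix(0, 0, 3))
  do.call(rbind, out)
}

# brute-force global virial (conservative pair + bond + angle) in R;
# angle part via numerically verified analytic decomposition is avoided --
# instead angle forces come from central finite differences of the energy,
# keeping this oracle independent of the C++ gradient.
brute_global_virial <- function(state, table, rc = 1) {
  pos <- state$pos; box <- state$box; n <- nrow(pos)
  W <- c(0, 0, 0)
  pr <- brute_pairs(pos, box, rc)
  if (nrow(pr) > 0) {
    for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1]; j <- pr[k, 2]
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      a <- table[state$species[i], state$species[j]]
      W <- W + a * (1 - r / rc) / r * d^2
    }
  }
  tp <- state$topology
  if (!is.null(tp) && nrow(tp$bonds) > 0) {
    for (k in seq_len(nrow(tp$bonds))) {
      i <- tp$bonds$i[k]; j <- tp$bonds$j[k]
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      W <- W + tp$bonds$ks[k] * (1 - r / tp$bonds$rs[k]) / r * d^2
    }
  }
  if (!is.null(tp) && nrow(tp$angles) > 0) {
    ang_energy <- function(p, k) {
      u <- p[tp$angles$i[k], ] - p[tp$angles$j[k], ]
      v <- p[tp$angles$k[k], ] - p[tp$angles$j[k], ]
      u <- u - box * round(u / box); v <- v - box * round(v / box)
      th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
      tp$angles$ktheta[k] * (th - tp$angles$theta0[k])^2
    }
    h <- 1e-6
    for (k in seq_len(nrow(tp$angles))) {
      trip <- c(tp$angles$i[k], tp$angles$j[k], tp$angles$k[k])
      fr <- matrix(0, 3, 3)
      for (bi in 1:3) for (dd in 1:3) {
        pp <- pos; pp[trip[bi], dd] <- pp[trip[bi], dd] + h
        pm <- pos; pm[trip[bi], dd] <- pm[trip[bi], dd] - h
        fr[bi, dd] <- -(ang_energy(pp, k) - ang_energy(pm, k)) / (2 * h)
      }
      uj <- pos[trip[1], ] - pos[trip[2], ]
      uj <- uj - box * round(uj / box)
      vj <- pos[trip[3], ] - pos[trip[2], ]
      vj <- vj - box * round(vj / box)
      W <- W + fr[1, ] * uj + fr[3, ] * vj
    }
  }
  (colSums(state$vel^2) + W) / prod(box)
}

# a single-molecule state at arbitrary coordinates
molecule_state <- function(top, pos, box = c(10, 10, 10), vel = NULL) {
  n <- length(top$species)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  dpdlipid:::new_dpd_state(
    pos, vel, top$species, rep(1L, n), box,
    topology = list(
      bonds = top$bonds, angles = top$angles,
      molecules = tibble::tibble(mol = 1L, type = top$type, first = 1L,
                                 n_beads = n, n_head = top$n_head)))
}

# two free beads of given species at distance r along x, no topology
two_bead_state <- function(r, species = c(1L, 1L), box = c(10, 10, 10),
                           vel = matrix(0, 2, 3)) {
  dpdlipid:::new_dpd_state(
    rbind(c(5, 5, 5), c(5 + r, 5, 5)), vel, species, c(0L, 0L), box)
}

# a state of n_chain straight head-only chains with given unit directions;
# used by the order-parameter tests
aligned_chain_state <- function(dirs, n_head = 3, box = c(20, 20, 20),
                                spacing = 0.4) {
  n_chain <- nrow(dirs)
  n <- n_chain * n_head
  set.seed(99)
  base <- matrix(runif(3 * n_chain), n_chain, 3) %*% diag(box - 3) + 1.5
  off <- rep(seq_len(n_head) - 1, times = n_chain) * spacing
  pos <- base[rep(seq_len(n_chain), each = n_head), ] +
    off * dirs[rep(seq_len(n_chain), each = n_head), ]
  dpdlipid:::new_dpd_state(
    pos, matrix(0, n, 3), rep(2L, n), rep(seq_len(n_chain), each = n_head),
    box,
    topology = list(
      bonds = tibble::tibble(i = integer(), j = integer(),
                             ks = numeric(), rs = numeric()),
      angles = tibble::tibble(i = integer(), j = integer(), k = integer(),
                              ktheta = numeric(), theta0 = numeric()),
      molecules = tibble::tibble(mol = seq_len(n_chain), type = 1L,
                                 first = (seq_len(n_chain) - 1) * n_head + 1L,
                                 n_beads = n_head, n_head = n_head)))
}

water_config <- function(box, seed = 1, ...) {
  run_config(box = box, n1 = 0, n2 = 0, total_steps = 0, seed = seed, ...)
}
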