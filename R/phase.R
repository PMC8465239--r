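#' Classify a configuration as membrane, tube or vesicle
#'
#' Builds the connectivity graph of all tail beads with link distance
#' `cutoff` (the interaction range) under periodic boundaries, takes the
#' largest connected cluster, and tests it for percolation across each box
#' axis by tracking image offsets while walking the cluster: a closed walk
#' that returns to a bead through a different periodic image spans that
#' axis. A cluster spanning two or more axes is a `MEMBRANE`, exactly one a
#' `TUBE`. A non-spanning cluster is a `VESICLE` when its beads cover the
#' full solid angle around the cluster centre at a radius comparable to
#' the cluster size (closed-shell test -- compact micelles pass it too and
#' are deliberately labelled `VESICLE`); anything else is `OTHER`.
#'
#' The rule is deterministic and invariant under periodic translation and
#' axis permutation of the state.
#'
#' @param state A `dpd_state` containing tail beads.
#' @param cutoff Clustering distance in rc (default 1, the interaction
#'   range).
#' @param coverage_threshold Fraction of the 26 direction sectors that must
#'   contain far-shell cluster beads for the closed-shell test (default
#'   0.85).
#' @return An object of class `phase_label`: `label` (one of `"MEMBRANE"`,
#'   `"TUBE"`, `"VESICLE"`, `"OTHER"`) and an `evidence` list (cluster
#'   size and count, axes spanned, shell coverage, enclosed-water flag).
#' @export
classify_structure <- function(state, cutoff = 1, coverage_threshold = 0.85) {
  stopifnot(inherits(state, "dpd_state"))
  tail_idx <- which(state$species %in%
                      species_code(c("T1", "T2")))
  if (length(tail_idx) == 0) abort("no lipid tail beads to classify")
  pos <- state$pos[tail_idx, , drop = FALSE]
  box <- state$box
  n <- nrow(pos)
  pr <- cpp_neighbor_pairs(pos, box, cutoff)
  adj_i <- c(pr$i, pr$j)
  adj_j <- c(pr$j, pr$i)
  adj_d <- rbind(cbind(pr$dx, pr$dy, pr$dz), -cbind(pr$dx, pr$dy, pr$dz))
  ord <- order(adj_i)
  adj_i <- adj_i[ord]; adj_j <- adj_j[ord]
  adj_d <- adj_d[ord, , drop = FALSE]
  starts <- c(match(seq_len(n), adj_i), length(adj_i) + 1L)
  starts[is.na(starts)] <- 0L
  # forward-fill the CSR starts for isolated beads
  nxt <- length(adj_i) + 1L
  for (k in rev(seq_len(n))) {
    if (starts[k] == 0L) starts[k] <- nxt else nxt <- starts[k]
  }
  comp <- integer(n)
  unwrapped <- matrix(NA_real_, n, 3)
  spans <- list()
  ncomp <- 0L
  stack <- integer(n)
  for (root in seq_len(n)) {
    if (comp[root] != 0L) next
    ncomp <- ncomp + 1L
    span <- c(FALSE, FALSE, FALSE)
    comp[root] <- ncomp
    unwrapped[root, ] <- pos[root, ]
    stack[1] <- root
    top <- 1L
    while (top > 0L) {
      i <- stack[top]
      top <- top - 1L
      lo <- starts[i]
      hi <- starts[i + 1L] - 1L
      if (lo > hi) next
      for (e in lo:hi) {
        j <- adj_j[e]
        cand <- unwrapped[i, ] - adj_d[e, ]  # d = r_i - r_j
        if (comp[j] == 0L) {
          comp[j] <- ncomp
          unwrapped[j, ] <- cand
          top <- top + 1L
          stack[top] <- j
        } else {
          gap <- unwrapped[j, ] - cand
          span <- span | abs(gap) > box / 2
        }
      }
    }
    spans[[ncomp]] <- span
  }
  sizes <- tabulate(comp, ncomp)
  main <- which.max(sizes)
  span <- spans[[main]]
  n_span <- sum(span)
  in_main <- comp == main
  label <- if (n_span >= 2) "MEMBRANE" else if (n_span == 1) "TUBE" else NULL
  coverage <- NA_real_
  enclosed_water <- NA
  if (is.null(label)) {
    u <- unwrapped[in_main, , drop = FALSE]
    com <- colMeans(u)
    d <- sweep(u, 2, com)
    r <- sqrt(rowSums(d^2))
    r90 <- stats::quantile(r, 0.9)
    shell <- r > pmax(0.5 * r90, 1e-8)
    coverage <- if (!any(shell)) 0 else {
      dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      dirs <- dirs[rowSums(abs(dirs)) > 0, ]
      dirs <- dirs / sqrt(rowSums(dirs^2))
      un <- d[shell, , drop = FALSE] / r[shell]
      sector <- max.col(un %*% t(dirs))
      length(unique(sector)) / nrow(dirs)
    }
    # any water bead close to the cluster centre (wrapped minimum image)
    w_idx <- which(state$species == species_code("W"))
    if (length(w_idx) > 0 && is.finite(r90) && r90 > 1) {
      dw <- sweep(state$pos[w_idx, , drop = FALSE], 2, com %% box)
      dw <- dw - rep(box, each = nrow(dw)) * round(dw / rep(box, each = nrow(dw)))
      enclosed_water <- any(sqrt(rowSums(dw^2)) < 0.5 * r90)
    }
    label <- if (coverage >= coverage_threshold) "VESICLE" else "OTHER"
  }
  structure(list(label = label,
                 evidence = list(cluster_size = sizes[main],
                                 n_clusters = ncomp,
                                 spanned_axes = c("x", "y", "z")[span],
                                 shell_coverage = coverage,
                                 enclosed_water = enclosed_water)),
            class = "phase_label")
}

#' @export
print.phase_label <- function(x, ...) {
  ev <- x$evidence
  cat("<phase_label> ", x$label, " (cluster ", ev$cluster_size, "/",
      ev$n_clusters, " clusters; spans ",
      if (length(ev$spanned_axes)) paste(ev$spanned_axes, collapse = ",")
      else "none", ")\n", sep = "")
  invisible(x)
}

#' Reduced-scale phase sweep over tail lengths
#'
#' Runs one short self-assembly simulation per `(NT1, NT2, seed)` cell at a
#' reduced scale, classifies the final configuration, and records the label
#' and final potential energy. Cells that error are recorded as failed and
#' the sweep continues. The default scale (box 15 rc, 150 + 150 lipids) is
#' an approximation chosen to keep a grid affordable, not the production
#' scale.
#'
#' @param nt1,nt2 Tail-length grids (type-1 tail beads; type-2 beads per
#'   tail).
#' @param seeds Seeds per cell.
#' @param box,n1,n2 Reduced-scale system size.
#' @param steps Steps per cell.
#' @param swap_interval Shear setting (`Inf`, 6, 1, ...).
#' @param interaction_mode Passed to [interaction_table()].
#' @param params A [dpd_params()].
#' @param progress Print one line per completed cell.
#' @return A tibble of class `phase_diagram` with one row per
#'   `(nt1, nt2, seed)`: `label`, `potential`, `failed`, plus the evidence
#'   columns `cluster_size` and `spans`.
#' @export
phase_sweep <- function(nt1 = c(2, 6, 10), nt2 = c(2, 6, 10), seeds = 1,
                        box = 15, n1 = 150, n2 = 150, steps = 50000,
                        swap_interval = Inf,
                        interaction_mode = "amphiphilic",
                        params = dpd_params(), progress = FALSE) {
  grid <- tidyr::expand_grid(nt1 = nt1, nt2 = nt2, seed = seeds)
  tab <- interaction_table(interaction_mode)
  rows <- purrr::pmap(grid, function(nt1, nt2, seed) {
    res <- tryCatch({
      cfg <- run_config(box = box, n1 = n1, n2 = n2, nt1 = nt1, nt2 = nt2,
                        total_steps = steps, swap_interval = swap_interval,
                        seed = seed, interaction_mode = interaction_mode,
                        params = params)
      st <- random_initial_configuration(cfg)
      run <- run_dpd(st, steps, table = tab, params = params, seed = seed,
                     swap_interval = swap_interval, n_slabs = cfg$n_slabs)
      lab <- classify_structure(run$state)
      en <- total_energy(run$state, tab, params)
      tibble(nt1 = nt1, nt2 = nt2, seed = seed, label = lab$label,
             potential = en$potential,
             cluster_size = lab$evidence$cluster_size,
             spans = length(lab$evidence$spanned_axes), failed = FALSE)
    }, error = function(e) {
      tibble(nt1 = nt1, nt2 = nt2, seed = seed, label = NA_character_,
             potential = NA_real_, cluster_size = NA_integer_,
             spans = NA_integer_, failed = TRUE)
    })
    if (progress)
      message(sprintf("cell nt1=%d nt2=%d seed=%d -> %s",
                      nt1, nt2, seed, res$label %||% "FAILED"))
    res
  })
  structure(bind_rows(rows), class = c("phase_diagram", class(grid)))
}

#' Modal label per phase-diagram cell
#'
#' Summarises a [phase_sweep()] result to one row per `(nt1, nt2)` cell:
#' the most frequent label across seeds, the number of seeds, and whether
#' all seeds agreed.
#'
#' @param diagram A `phase_diagram`.
#' @return A tibble with `nt1`, `nt2`, `label`, `n_seeds`, `agreement`.
#' @export
modal_phase <- function(diagram) {
  diagram |>
    filter(!.data$failed) |>
    group_by(.data$nt1, .data$nt2) |>
    summarise(label = names(which.max(table(.data$label))),
              n_seeds = dplyr::n(),
              agreement = max(table(.data$label)) / dplyr::n(),
              .groups = "drop")
}
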