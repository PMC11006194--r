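# Symmetry-lumped absorbing chains.
#
# The constructors for the structured families (complete, star, fan, and
# the composite amplifier) record an orbit description of their node
# symmetries with three kinds of components:
#   singletons — designated nodes tracked individually (star center, fan
#                center, the connecting-edge endpoints u and v);
#   counts     — interchangeable node classes tracked by mutant count
#                (complete-graph nodes, star leaves, hub nodes);
#   pairs      — interchangeable two-node blades tracked by (number of
#                blades with exactly one mutant, number fully mutant).
# A configuration's class is the vector of these components. Because the
# partition comes from weight-preserving automorphisms, all members of a
# class share the same outgoing class-transition law (strong lumpability);
# this is verified at solve time from a second member of each class rather
# than assumed, and the solver refuses if the check fails.

orbit_map <- function(orbits, N) {
  type <- integer(N); pos <- integer(N); partner <- rep(NA_integer_, N)
  cp <- 0L
  for (s in orbits$singletons) {
    cp <- cp + 1L
    type[s] <- 1L; pos[s] <- cp
  }
  for (grp in orbits$counts) {
    cp <- cp + 1L
    type[grp] <- 2L; pos[grp] <- cp
  }
  for (P in orbits$pairs) {
    type[P] <- 3L; pos[P] <- cp + 1L
    partner[P[, 1L]] <- P[, 2L]
    partner[P[, 2L]] <- P[, 1L]
    cp <- cp + 2L
  }
  if (any(type == 0L)) abort_invariant("orbit description does not cover all nodes")
  list(type = type, pos = pos, partner = partner, ncomp = cp)
}

base_components <- function(mem, orbits) {
  comps <- integer(0)
  for (s in orbits$singletons) comps <- c(comps, as.integer(mem[s]))
  for (grp in orbits$counts) comps <- c(comps, sum(mem[grp]))
  for (P in orbits$pairs) {
    s <- mem[P[, 1L]] + mem[P[, 2L]]
    comps <- c(comps, sum(s == 1L), sum(s == 2L))
  }
  comps
}

paste_keys <- function(mat) {
  do.call(paste, c(lapply(seq_len(ncol(mat)), function(j) mat[, j]), sep = ","))
}

# Class keys of the configurations reached from `mem` by flipping node
# `to[i]` to the type of node `from[i]` (vectorized over events).
target_components <- function(mem, from, to, omap, base) {
  n_ev <- length(to)
  gain <- mem[from]
  comp <- matrix(rep(base, each = n_ev), nrow = n_ev)
  typ <- omap$type[to]; pos <- omap$pos[to]
  i1 <- which(typ == 1L)
  if (length(i1)) comp[cbind(i1, pos[i1])] <- as.integer(gain[i1])
  i2 <- which(typ == 2L)
  if (length(i2)) comp[cbind(i2, pos[i2])] <- base[pos[i2]] + ifelse(gain[i2], 1L, -1L)
  i3 <- which(typ == 3L)
  if (length(i3)) {
    pmut <- mem[omap$partner[to[i3]]]
    gi <- gain[i3]
    dn1 <- ifelse(xor(gi, pmut), 1L, -1L)
    dn2 <- ifelse(pmut, ifelse(gi, 1L, -1L), 0L)
    comp[cbind(i3, pos[i3])] <- comp[cbind(i3, pos[i3])] + dn1
    comp[cbind(i3, pos[i3] + 1L)] <- comp[cbind(i3, pos[i3] + 1L)] + dn2
  }
  comp
}

# Conditional (configuration-changing) class-transition law from the class
# of `mem`: named probability vector over target class keys, with "FIX"
# and "EXT" for the absorbing classes. Also returns per-event data so the
# caller can construct representative members of newly seen classes.
class_transitions <- function(g, mem, process, omap, orbits) {
  ev <- event_probs(g, mem, process)
  ch <- which(ev$changes)
  p <- ev$p[ch]
  p <- p / sum(p)
  from <- ev$from[ch]; to <- ev$to[ch]
  gain <- mem[from]
  base <- base_components(mem, orbits)
  keys <- paste_keys(target_components(mem, from, to, omap, base))
  knew <- sum(mem) + ifelse(gain, 1L, -1L)
  keys[knew == n_nodes(g)] <- "FIX"
  keys[knew == 0L] <- "EXT"
  agg <- vapply(split(p, keys), sum, numeric(1))
  list(agg = agg, keys = keys, to = to, gain = gain)
}

# Enumerate all classes reachable from the seed configurations and solve
# the lumped absorption system.
lumped_chain_solution <- function(g, process, extra_seeds = list(),
                                  check_lumpability = TRUE, check_tol = 1e-9) {
  require_connected(g)
  orbits <- g$meta$orbits
  if (is.null(orbits)) {
    abort_family(paste0(
      "graph carries no orbit (family) structure; lumped solving supports ",
      "graphs built by make_complete(), make_star(), make_fan(), make_amplifier_an()"))
  }
  N <- n_nodes(g)
  omap <- orbit_map(orbits, N)
  key_of <- function(mem) paste(base_components(mem, orbits), collapse = ",")

  reps <- new.env(parent = emptyenv())
  alts <- new.env(parent = emptyenv())
  cap <- 4096L
  queue <- vector("list", cap)   # configurations to expand
  qkeys <- character(cap)
  n_q <- 0L
  push <- function(mem, key) {
    if (n_q == cap) {
      cap <<- cap * 2L
      length(queue) <<- cap
      length(qkeys) <<- cap
    }
    n_q <<- n_q + 1L
    queue[[n_q]] <<- mem
    qkeys[n_q] <<- key
  }

  node_keys <- character(N)
  for (v in seq_len(N)) {
    mem <- logical(N); mem[v] <- TRUE
    kk <- key_of(mem)
    node_keys[v] <- kk
    if (is.null(reps[[kk]])) { reps[[kk]] <- mem; push(mem, kk) }
  }
  for (mem in extra_seeds) {
    k <- sum(mem)
    if (k == 0L || k == N) next
    kk <- key_of(mem)
    if (is.null(reps[[kk]])) { reps[[kk]] <- mem; push(mem, kk) }
  }

  trans <- vector("list", n_q)
  head <- 1L
  while (head <= n_q) {
    mem <- queue[[head]]
    tr <- class_transitions(g, mem, process, omap, orbits)
    trans[[head]] <- tr$agg
    new_keys <- setdiff(names(tr$agg), c("FIX", "EXT"))
    for (kk in new_keys) {
      i <- which(tr$keys == kk)[1L]
      mem2 <- mem
      mem2[tr$to[i]] <- tr$gain[i]
      if (is.null(reps[[kk]])) {
        reps[[kk]] <- mem2
        push(mem2, kk)
      } else if (check_lumpability && is.null(alts[[kk]]) &&
                 !identical(mem2, reps[[kk]])) {
        alts[[kk]] <- mem2
      }
    }
    head <- head + 1L
  }
  classes <- qkeys[seq_len(n_q)]
  trans <- trans[seq_len(n_q)]

  if (check_lumpability) {
    for (kk in ls(alts)) {
      i <- match(kk, classes)
      tr2 <- class_transitions(g, alts[[kk]], process, omap, orbits)$agg
      ref <- trans[[i]]
      keys_all <- union(names(ref), names(tr2))
      d <- abs(ifelse(is.na(ref[keys_all]), 0, ref[keys_all]) -
               ifelse(is.na(tr2[keys_all]), 0, tr2[keys_all]))
      if (max(d) > check_tol) {
        abort_invariant(sprintf(
          "state lumping is not exact for class [%s] (max transition mismatch %.3g); refusing to solve",
          kk, max(d)))
      }
    }
  }

  ns <- length(classes)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  b <- numeric(ns)
  for (i in seq_len(ns)) {
    agg <- trans[[i]]
    nm <- names(agg)
    if ("FIX" %in% nm) b[i] <- agg[["FIX"]]
    keep <- !(nm %in% c("FIX", "EXT"))
    if (any(keep)) {
      ti <- c(ti, rep.int(i, sum(keep)))
      tj <- c(tj, match(nm[keep], classes))
      tx <- c(tx, unname(agg[keep]))
    }
  }
  Q <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ns, ns))
  A <- Matrix::Diagonal(ns) - Q
  h <- as.numeric(Matrix::solve(A, b))
  residual <- max(abs(as.numeric(A %*% h) - b))
  list(classes = classes, h = h,
       h_of_key = setNames(h, classes),
       node_keys = node_keys, residual = residual, n_classes = ns)
}

#' Fixation probability via a symmetry-lumped chain
#'
#' Solves the absorbing chain on symmetry classes of configurations
#' instead of the full \eqn{2^N} space. Supported for graphs built by
#' [make_complete()], [make_star()], [make_fan()] and
#' [make_amplifier_an()], whose constructors record the orbit structure of
#' their node symmetries (for the composite amplifier the tracked state is
#' the type of each connecting-edge endpoint, the mutant count among the
#' remaining hub nodes, and the blade occupancy counts of both chunks).
#' Exact lumpability is verified during the solve from alternative class
#' members; if the check fails the solver refuses rather than
#' approximates.
#'
#' @inheritParams solve_fixation_exact
#' @param check_lumpability Verify the class-transition law from a second
#'   member of each class (default `TRUE`; roughly doubles the work).
#' @return A `fixation_result` with `method = "lumped"`; `$n_classes`
#'   reports the lumped state-space size.
#' @export
#' @examples
#' solve_fixation_lumped(make_star(11), moran_process("Bd", 1.05))
solve_fixation_lumped <- function(g, process, init = "uniform",
                                  check_lumpability = TRUE) {
  N <- n_nodes(g)
  extra <- list()
  if (!identical(init, "uniform")) {
    extra <- list(as_membership(g, init))
  }
  sol <- lumped_chain_solution(g, process, extra_seeds = extra,
                               check_lumpability = check_lumpability)
  p <- if (identical(init, "uniform")) {
    mean(sol$h_of_key[sol$node_keys])
  } else {
    mem <- as_membership(g, init)
    k <- sum(mem)
    if (k == 0L) 0 else if (k == N) 1 else {
      sol$h_of_key[[paste(base_components(mem, g$meta$orbits), collapse = ",")]]
    }
  }
  fixation_result(probability = unname(p), method = "lumped",
                  residual = sol$residual, n_classes = sol$n_classes,
                  kind = process$kind, r = process$r,
                  init = if (identical(init, "uniform")) "uniform" else paste(init, collapse = ","))
}
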