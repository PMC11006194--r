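# Single-step kernels for the two Moran update rules, and seeded Monte
# Carlo estimation of fixation probabilities (compiled trajectory engine).

#' Specify a Moran process
#'
#' @param kind `"Bd"` (Birth-death: fitness-proportional reproduction,
#'   offspring replaces a weight-proportional random neighbour) or `"dB"`
#'   (death-Birth: uniform death, neighbours compete for the vacancy with
#'   probability proportional to fitness times edge weight).
#' @param r Relative mutant fitness (> 0); residents have fitness 1.
#' @return An object of class `moran_process`.
#' @export
#' @examples
#' moran_process("Bd", r = 1.1)
moran_process <- function(kind = c("Bd", "dB"), r = 1) {
  kind <- match.arg(kind)
  r <- check_scalar_positive(r, "r")
  structure(list(kind = kind, r = r), class = "moran_process")
}

#' @export
print.moran_process <- function(x, ...) {
  cat(sprintf("<moran_process> %s updating, r = %g\n", x$kind, x$r))
  invisible(x)
}

as_membership <- function(g, mutants) {
  n <- n_nodes(g)
  if (is.logical(mutants)) {
    if (length(mutants) != n) abort_validation("logical mutant set must have length N")
    return(mutants)
  }
  mem <- logical(n)
  if (length(mutants)) mem[node_index(g, mutants)] <- TRUE
  mem
}

# Core one-step event probabilities. Returns parallel vectors over all
# directed replacement events (source from, target to), their
# probabilities, and whether each event changes the configuration.
# Probabilities over all events sum to 1 for either update rule.
event_probs <- function(g, mem, process) {
  r <- process$r
  ed <- g$ed
  fu <- ifelse(mem[ed$from], r, 1)
  if (process$kind == "Bd") {
    Ftot <- sum(ifelse(mem, r, 1))
    p <- fu * ed$w / (Ftot * g$deg[ed$from])
  } else {
    denom <- g$deg + (r - 1) * as.numeric(mem %*% g$W)
    p <- fu * ed$w / (n_nodes(g) * denom[ed$to])
  }
  list(from = ed$from, to = ed$to, p = p, changes = mem[ed$from] != mem[ed$to])
}

#' One-step replacement distribution
#'
#' Enumerates every directed replacement event (source reproduces into
#' target) with its probability under the chosen update rule, from the
#' given mutant configuration.
#'
#' @param g A connected `weighted_graph`.
#' @param mutants Mutant set: character vector of node labels, or a
#'   logical membership vector of length N. Must not be absorbing (empty
#'   or full).
#' @param process A [moran_process()].
#' @return A data frame with columns `source`, `target`, `probability`,
#'   `changes` (does the event flip the target's type?). The aggregate
#'   no-change mass is attached as attribute `"no_change"`.
#' @export
#' @examples
#' g <- make_complete(3)
#' replacement_distribution(g, "v1", moran_process("Bd", r = 2))
replacement_distribution <- function(g, mutants, process) {
  require_connected(g)
  mem <- as_membership(g, mutants)
  k <- sum(mem)
  if (k == 0L || k == n_nodes(g)) {
    abort_absorbing("the configuration is absorbing (no mutants, or all mutants)")
  }
  ev <- event_probs(g, mem, process)
  out <- data.frame(source = g$nodes[ev$from], target = g$nodes[ev$to],
                    probability = ev$p, changes = ev$changes,
                    stringsAsFactors = FALSE)
  attr(out, "no_change") <- sum(ev$p[!ev$changes])
  out
}

#' Apply one Moran step
#'
#' Samples a single replacement event by inverse CDF over the event list
#' (using the ambient R random number stream) and applies it: at most one
#' node changes type.
#'
#' @inheritParams replacement_distribution
#' @return The new mutant set as a character vector of node labels.
#' @export
moran_step <- function(g, mutants, process) {
  require_connected(g)
  mem <- as_membership(g, mutants)
  k <- sum(mem)
  if (k == 0L || k == n_nodes(g)) {
    abort_absorbing("the configuration is absorbing (no mutants, or all mutants)")
  }
  ev <- event_probs(g, mem, process)
  i <- sample.int(length(ev$p), 1L, prob = ev$p)
  mem[ev$to[i]] <- mem[ev$from[i]]
  g$nodes[mem]
}

adjacency_lists <- function(g) {
  nbr <- vector("list", n_nodes(g))
  nbw <- vector("list", n_nodes(g))
  for (i in seq_len(n_nodes(g))) {
    j <- which(g$W[i, ] > 0)
    nbr[[i]] <- as.integer(j)
    nbw[[i]] <- as.numeric(g$W[i, j])
  }
  list(nbr = nbr, nbw = nbw)
}

#' Monte Carlo fixation probability
#'
#' Runs seeded independent trajectories of the chosen Moran process to
#' absorption with a compiled inverse-CDF sampler (one event per step, no
#' caching across steps) and reports the fraction that fixed, with a
#' binomial standard error. Replicates that hit `max_steps` before
#' absorbing are reported separately in `$capped` and excluded from the
#' estimate — never silently counted.
#'
#' @param g A connected `weighted_graph`.
#' @param init `"uniform"` (a single initial mutant drawn uniformly at
#'   random, independently per replicate) or a character vector of node
#'   labels used as the fixed initial mutant set for every replicate.
#' @param process A [moran_process()].
#' @param replicates Number of independent trajectories (>= 1).
#' @param seed Optional integer seed; recorded in the result. The
#'   caller's RNG state is preserved.
#' @param max_steps Step cap per trajectory; default unlimited.
#' @return A `fixation_result` with `method = "monte-carlo"`: fields
#'   `probability`, `std_error`, `replicates`, `completed`, `capped`,
#'   `seed`, `mean_steps`.
#' @export
#' @examples
#' g <- make_complete(6)
#' estimate_fixation_probability(g, "uniform", moran_process("Bd", 1.5),
#'                               replicates = 2000, seed = 1)
estimate_fixation_probability <- function(g, init = "uniform", process,
                                          replicates = 10000, seed = NULL,
                                          max_steps = Inf) {
  require_connected(g)
  replicates <- check_scalar_count(replicates, "replicates", min = 1)
  if (!is.numeric(max_steps) || length(max_steps) != 1L || max_steps <= 0) {
    abort_validation("`max_steps` must be a positive number (Inf for no cap)")
  }
  al <- adjacency_lists(g)
  n <- n_nodes(g)
  with_preserved_seed(seed, {
    inits <- if (identical(init, "uniform")) {
      as.list(sample.int(n, replicates, replace = TRUE))
    } else {
      rep(list(node_index(g, init)), replicates)
    }
    sim <- mc_fixation_cpp(al$nbr, al$nbw, g$deg, process$kind == "Bd",
                           process$r, inits, as.numeric(max_steps))
    done <- !is.na(sim$outcome)
    ncomp <- sum(done)
    p <- if (ncomp) mean(sim$outcome[done]) else NA_real_
    se <- if (ncomp) sqrt(p * (1 - p) / ncomp) else NA_real_
    fixation_result(
      probability = p, method = "monte-carlo", std_error = se,
      replicates = replicates, completed = ncomp,
      capped = replicates - ncomp, seed = seed,
      mean_steps = mean(sim$steps), kind = process$kind, r = process$r,
      init = if (identical(init, "uniform")) "uniform" else paste(init, collapse = ",")
    )
  })
}

fixation_result <- function(probability, method, ...) {
  structure(c(list(probability = probability, method = method), list(...)),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat(sprintf("<fixation_result> rho = %.8g  [%s, %s updating, r = %g]\n",
              x$probability, x$method,
              if (!is.null(x$kind)) x$kind else "?",
              if (!is.null(x$r)) x$r else NA))
  if (identical(x$method, "monte-carlo")) {
    cat(sprintf("  replicates = %d (completed %d, capped %d), std. error = %.3g\n",
                x$replicates, x$completed, x$capped, x$std_error))
  }
  invisible(x)
}
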