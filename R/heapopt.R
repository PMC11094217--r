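# Heap-based optimizer (HO): a population metaheuristic that mirrors a
# corporate hierarchy. Agents are arranged in a d-ary min-heap keyed by
# fitness; each agent updates toward its heap parent (its "boss"), a sibling
# "colleague", or stays put, selected by a roulette whose segments shift
# from exploration to exploitation over the run. Moves are accepted only
# when strictly better (greedy), so the incumbent never degrades.

#' Heap-optimizer configuration
#'
#' @param population_size Number of search agents K (>= 2).
#' @param max_iterations Iteration count P (>= 1).
#' @param lower_bounds,upper_bounds Numeric vectors (length = problem
#'   dimension G) with `lower < upper` elementwise.
#' @param heap_degree Children per heap node (>= 2); ternary by default.
#' @param cycles Number of periods C of the gamma schedule; default
#'   `max(1, floor(P / 25))`.
#' @param per_agent_roulette If `TRUE`, one roulette draw governs all
#'   dimensions of a move; default is an independent draw per dimension.
#' @param init_position Optional numeric vector placed as the first agent
#'   (e.g. a structure-learned starting point); must lie within bounds.
#' @param init_spread Optional warm-start radius: when given together with
#'   `init_position`, the remaining agents start at `init_position` plus a
#'   uniform perturbation of `init_spread` times the box width per
#'   dimension (clipped), so the population refines a known solution
#'   instead of sampling the whole box.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return An `ho_config` list.
#' @export
ho_config <- function(population_size = 30, max_iterations = 100,
                      lower_bounds, upper_bounds, heap_degree = 3,
                      cycles = NULL, per_agent_roulette = FALSE,
                      init_position = NULL, init_spread = NULL, seed = 1L) {
  K <- as.integer(population_size); P <- as.integer(max_iterations)
  if (K < 2) stop("population_size must be >= 2", call. = FALSE)
  if (P < 1) stop("max_iterations must be >= 1", call. = FALSE)
  lb <- as.numeric(lower_bounds); ub <- as.numeric(upper_bounds)
  if (length(lb) != length(ub) || any(lb >= ub))
    stop("bounds must satisfy lower < upper elementwise", call. = FALSE)
  if (heap_degree < 2) stop("heap_degree must be >= 2", call. = FALSE)
  if (is.null(cycles)) cycles <- max(1L, P %/% 25L)
  if (!is.null(init_position)) {
    init_position <- as.numeric(init_position)
    if (length(init_position) != length(lb))
      stop("init_position has wrong length", call. = FALSE)
    init_position <- pmin(pmax(init_position, lb), ub)
  }
  if (!is.null(init_spread) && (is.null(init_position) || init_spread <= 0))
    stop("init_spread requires init_position and must be > 0", call. = FALSE)
  structure(list(K = K, P = P, G = length(lb), lower = lb, upper = ub,
                 heap_degree = as.integer(heap_degree),
                 cycles = as.integer(cycles),
                 per_agent_roulette = isTRUE(per_agent_roulette),
                 init_position = init_position, init_spread = init_spread,
                 seed = as.integer(seed)),
            class = "ho_config")
}

#' Periodic gamma control schedule
#'
#' \eqn{\gamma = |2 - (p \bmod \lceil P/C\rceil) / \lceil P/(4C)\rceil|}:
#' within each cycle the step coefficient decreases from 2 towards 0 and
#' climbs back, alternating exploitation and exploration.
#'
#' @param p Current iteration (1..P).
#' @param P Maximum iterations.
#' @param C Number of cycles.
#' @return Non-negative scalar.
#' @export
gamma_schedule <- function(p, P, C) {
  period <- ceiling(P / C)
  quarter <- ceiling(P / (4 * C))
  abs(2 - (p %% period) / quarter)
}

#' Roulette segment boundaries
#'
#' Cumulative probabilities `(o1, o2, o3)` of the keep / follow-parent /
#' follow-colleague branches: `o1 = 1 - p/P` shrinks linearly so the keep
#' branch dominates early and move branches dominate late; the remainder is
#' split evenly, `o2 = o1 + (1 - o1)/2`, `o3 = 1`.
#'
#' @param p Current iteration (1..P).
#' @param P Maximum iterations.
#' @return Numeric vector `c(o1, o2, o3)`, monotone within \[0, 1\].
#' @export
roulette_thresholds <- function(p, P) {
  o1 <- 1 - p / P
  c(o1 = o1, o2 = o1 + (1 - o1) / 2, o3 = 1)
}

# ---- d-ary heap over agent indices, keyed by fitness ---------------------
# state$heap[j]  = agent occupying heap node j
# state$node[i]  = heap node occupied by agent i
# ties broken by agent index so the ordering is total and deterministic

heap_less <- function(state, a, b) {
  fa <- state$fitness[a]; fb <- state$fitness[b]
  fa < fb || (fa == fb && a < b)
}

heap_swap <- function(state, na, nb) {
  ia <- state$heap[na]; ib <- state$heap[nb]
  state$heap[na] <- ib; state$heap[nb] <- ia
  state$node[ib] <- na; state$node[ia] <- nb
  state
}

heap_sift_up <- function(state, n) {
  d <- state$degree
  while (n > 1L) {
    par <- (n - 2L) %/% d + 1L
    if (heap_less(state, state$heap[n], state$heap[par])) {
      state <- heap_swap(state, n, par)
      n <- par
    } else break
  }
  state
}

heap_sift_down <- function(state, n) {
  d <- state$degree; K <- length(state$heap)
  repeat {
    first <- d * (n - 1L) + 2L
    if (first > K) break
    kids <- first:min(first + d - 1L, K)
    best <- kids[1L]
    for (k in kids[-1L])
      if (heap_less(state, state$heap[k], state$heap[best])) best <- k
    if (heap_less(state, state$heap[best], state$heap[n])) {
      state <- heap_swap(state, n, best)
      n <- best
    } else break
  }
  state
}

heap_build <- function(state) {
  K <- length(state$heap)
  for (n in rev(seq_len(max(1L, (K - 2L) %/% state$degree + 1L))))
    state <- heap_sift_down(state, n)
  state
}

#' Verify the heap invariant of an optimizer state
#'
#' Full scan: every node's key must not exceed any child's key
#' (fitness, ties by agent index).
#'
#' @param state An HO state as produced by [ho_initialize()] / [ho_step()].
#' @return `TRUE` if the d-ary heap property holds everywhere.
#' @export
ho_check_heap <- function(state) {
  K <- length(state$heap); d <- state$degree
  for (n in seq_len(K)) {
    if (n > 1L) {
      par <- (n - 2L) %/% d + 1L
      if (heap_less(state, state$heap[n], state$heap[par])) return(FALSE)
    }
  }
  identical(sort(state$heap), seq_len(K)) &&
    all(state$node[state$heap] == seq_len(K))
}

#' Initialize the optimizer population
#'
#' Positions drawn uniformly within the bounds from the seeded generator
#' (agent 1 replaced by `cfg$init_position` when given), fitness evaluated,
#' heap built.
#'
#' @param cfg An [ho_config()].
#' @param f Objective: function from length-G numeric to finite scalar
#'   (minimized).
#' @return An HO state (list with positions, fitness, heap, best incumbents).
#' @export
ho_initialize <- function(cfg, f) {
  with_seed(cfg$seed, {
    K <- cfg$K; G <- cfg$G
    if (!is.null(cfg$init_position) && !is.null(cfg$init_spread)) {
      jit <- matrix(stats::runif(K * G, -cfg$init_spread, cfg$init_spread),
                    K, G)
      jit <- sweep(jit, 2, cfg$upper - cfg$lower, "*")
      pos <- sweep(jit, 2, cfg$init_position, "+")
      pos <- pmin(pmax(pos, matrix(cfg$lower, K, G, byrow = TRUE)),
                  matrix(cfg$upper, K, G, byrow = TRUE))
    } else {
      pos <- matrix(stats::runif(K * G), K, G)
      pos <- sweep(sweep(pos, 2, cfg$upper - cfg$lower, "*"), 2, cfg$lower,
                   "+")
    }
    if (!is.null(cfg$init_position)) pos[1L, ] <- cfg$init_position
    fit <- numeric(K)
    for (i in seq_len(K)) fit[i] <- f(pos[i, ])
    if (any(!is.finite(fit)))
      stop("objective returned a non-finite value at initialization",
           call. = FALSE)
    best <- which.min(fit)
    state <- list(positions = pos, fitness = fit,
                  heap = seq_len(K), node = seq_len(K),
                  degree = cfg$heap_degree, iteration = 0L,
                  best_position = pos[best, ], best_fitness = fit[best],
                  history = numeric(0),
                  rng = get(".Random.seed", envir = globalenv()))
    heap_build(state)
  })
}

#' Propose a candidate move for one agent
#'
#' Implements the four-branch update: per dimension, with roulette draw `o`
#' against the thresholds `(o1, o2, o3)`, the agent keeps its coordinate
#' (`o <= o1`), steps about its heap parent's coordinate
#' (`o1 < o <= o2`), or engages a colleague drawn from its parent's other
#' children — stepping about the colleague when the colleague is fitter,
#' else about itself with the colleague setting the step length. Steps are
#' `gamma * beta * |ref - x|` with `beta ~ U(-1, 1)`. The root, having no
#' parent, falls through to the colleague branches. The candidate is clipped
#' to the bounds.
#'
#' @param state HO state.
#' @param i Agent index.
#' @param gamma Schedule coefficient from [gamma_schedule()].
#' @param thresholds From [roulette_thresholds()].
#' @param cfg The run's [ho_config()].
#' @return Numeric candidate position of length G.
#' @export
ho_propose <- function(state, i, gamma, thresholds, cfg) {
  G <- ncol(state$positions)
  x <- state$positions[i, ]
  d <- state$degree
  n <- state$node[i]
  has_parent <- n > 1L
  if (has_parent) {
    par_node <- (n - 2L) %/% d + 1L
    parent <- state$heap[par_node]
    first <- d * (par_node - 1L) + 2L
    sibs <- state$heap[first:min(first + d - 1L, length(state$heap))]
    sibs <- sibs[sibs != i]
  } else {
    sibs <- integer(0)
  }
  colleague <- if (length(sibs)) {
    if (length(sibs) == 1L) sibs else sibs[sample.int(length(sibs), 1L)]
  } else {
    others <- setdiff(seq_len(nrow(state$positions)), i)
    others[sample.int(length(others), 1L)]
  }
  o <- if (cfg$per_agent_roulette) rep(stats::runif(1), G) else stats::runif(G)
  beta <- stats::runif(G, -1, 1)
  cand <- x
  keep <- o <= thresholds[1]
  to_parent <- !keep & o <= thresholds[2] & has_parent
  rest <- !keep & !to_parent
  if (any(to_parent)) {
    D <- state$positions[parent, ]
    cand[to_parent] <- D[to_parent] +
      gamma * beta[to_parent] * abs(D[to_parent] - x[to_parent])
  }
  if (any(rest)) {
    Nv <- state$positions[colleague, ]
    if (state$fitness[colleague] < state$fitness[i]) {
      cand[rest] <- Nv[rest] + gamma * beta[rest] * abs(Nv[rest] - x[rest])
    } else {
      cand[rest] <- x[rest] + gamma * beta[rest] * abs(Nv[rest] - x[rest])
    }
  }
  pmin(pmax(cand, cfg$lower), cfg$upper)
}

#' Advance the optimizer by one iteration
#'
#' Every agent proposes a move; a move is accepted only when its fitness is
#' strictly better, after which the heap is repaired and the incumbent
#' updated. The best-so-far history gains one (non-increasing) entry.
#'
#' @param state HO state.
#' @param f Objective (minimized).
#' @param cfg The run's [ho_config()].
#' @return Updated state.
#' @export
ho_step <- function(state, f, cfg) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_rng <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_rng, envir = globalenv()), add = TRUE)
  }
  assign(".Random.seed", state$rng, envir = globalenv())
  p <- state$iteration + 1L
  gamma <- gamma_schedule(p, cfg$P, cfg$cycles)
  thr <- roulette_thresholds(p, cfg$P)
  for (i in seq_len(cfg$K)) {
    cand <- ho_propose(state, i, gamma, thr, cfg)
    fc <- f(cand)
    if (!is.finite(fc)) {
      warning("non-finite candidate fitness for agent ", i,
              "; move rejected", call. = FALSE)
      next
    }
    if (fc < state$fitness[i]) {
      state$positions[i, ] <- cand
      state$fitness[i] <- fc
      state <- heap_sift_up(state, state$node[i])
      if (fc < state$best_fitness) {
        state$best_fitness <- fc
        state$best_position <- cand
      }
    }
  }
  state$iteration <- p
  state$history <- c(state$history, state$best_fitness)
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

#' Run the heap-based optimizer
#'
#' @param f Objective: length-G numeric -> finite scalar, minimized.
#'   Callers with a maximization objective pass its negation.
#' @param cfg An [ho_config()].
#' @return List with `best_position`, `best_fitness`, `history`
#'   (best-so-far per iteration, non-increasing) and the final `state`.
#' @export
ho_optimize <- function(f, cfg) {
  state <- ho_initialize(cfg, f)
  for (p in seq_len(cfg$P)) state <- ho_step(state, f, cfg)
  list(best_position = state$best_position,
       best_fitness = state$best_fitness,
       history = state$history, state = state)
}
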