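# Ground-truth linear non-Gaussian network data: every downstream stage of
# the pipeline is validated against structures generated here.

#' Generate a random weighted DAG
#'
#' Draws a uniformly random topological order over `p` nodes and selects
#' `round(density * p * (p - 1) / 2)` unordered pairs uniformly at random,
#' orienting each consistently with the order. Edge weights are drawn
#' uniformly from `[-weight_range[2], -weight_range[1]] U [weight_range[1],
#' weight_range[2]]`, strong enough for detection at typical resting-state
#' sample sizes but far from deterministic coupling.
#'
#' @param p node count (>= 2).
#' @param density fraction of unordered pairs to connect, in `[0, 1]`. The
#'   default 0.0225 mirrors the ~2.25% density of empirical causal
#'   connectomes.
#' @param weight_range length-2 numeric, magnitude range of edge weights.
#' @param seed integer seed.
#' @return An object of class `gango_dag`: list with `p`, `edges` (two-column
#'   integer matrix, row = directed edge from column 1 to column 2),
#'   `weights`, `order` (topological order), `nodes` (parcel ids).
#' @export
#' @examples
#' d <- generate_dag(10, density = 0.2, seed = 1)
#' nrow(d$edges)
generate_dag <- function(p, density = 0.0225, weight_range = c(0.3, 0.8),
                         seed = 1L) {
  if (p < 2) stopf("p must be >= 2, got %s", p)
  if (density < 0 || density > 1) {
    stopf("density must be in [0, 1], got %s", density)
  }
  n_edges <- round(density * p * (p - 1) / 2)
  with_seed(seed, {
    ord <- sample.int(p) # ord[k] = node at position k
    pos <- order(ord)    # pos[v] = position of node v
    edges <- matrix(integer(0), 0, 2)
    if (n_edges > 0) {
      idx <- sample.int(p * (p - 1) / 2, n_edges)
      all_pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
      pairs <- all_pairs[idx, , drop = FALSE]
      # orient each selected unordered pair along the topological order
      flip <- pos[pairs[, 1]] > pos[pairs[, 2]]
      edges <- cbind(ifelse(flip, pairs[, 2], pairs[, 1]),
                     ifelse(flip, pairs[, 1], pairs[, 2]))
    }
    w <- runif(n_edges, weight_range[1], weight_range[2]) *
      sample(c(-1, 1), n_edges, replace = TRUE)
    structure(
      list(p = as.integer(p), edges = matrix(as.integer(edges), ncol = 2),
           weights = w, order = ord, nodes = node_names(p)),
      class = "gango_dag")
  })
}

noise_families <- c("exponential", "gamma", "gaussian")

#' Specify the noise distribution of the structural equation model
#'
#' Exponential and gamma noise are skewed (the regime the orientation stage
#' requires); Gaussian noise is the negative control under which causal
#' direction is unidentifiable.
#'
#' @param family one of `"exponential"`, `"gamma"`, `"gaussian"`.
#' @param rate,shape,scale family parameters (exponential uses `rate`,
#'   gamma uses `shape` and `scale`).
#' @param standardize centre and scale draws to zero mean, unit variance
#'   (default `TRUE`).
#' @return An object of class `gango_noise`.
#' @export
noise_spec <- function(family = c("exponential", "gamma", "gaussian"),
                       rate = 1, shape = 2, scale = 1, standardize = TRUE) {
  family <- match.arg(family)
  structure(list(family = family, rate = rate, shape = shape, scale = scale,
                 standardize = standardize),
            class = "gango_noise")
}

draw_noise <- function(noise, n) {
  x <- switch(noise$family,
    exponential = rexp(n, rate = noise$rate),
    gamma = rgamma(n, shape = noise$shape, scale = noise$scale),
    gaussian = rnorm(n),
    stopf("unknown noise family '%s'", noise$family))
  if (isTRUE(noise$standardize)) {
    mu <- switch(noise$family,
      exponential = 1 / noise$rate,
      gamma = noise$shape * noise$scale,
      gaussian = 0)
    sigma <- switch(noise$family,
      exponential = 1 / noise$rate,
      gamma = sqrt(noise$shape) * noise$scale,
      gaussian = 1)
    x <- (x - mu) / sigma
  }
  x
}

#' Simulate i.i.d. samples from a linear non-Gaussian acyclic model
#'
#' Each sample solves `x = B x + e` by substitution in topological order:
#' node values are its parents' weighted values plus an independent noise
#' draw. Rows are exchangeable observations (no temporal autocorrelation),
#' matching the assumptions of the score-based search and pairwise
#' orientation stages; `ar` optionally colors the noise with an AR(1)
#' filter for sensitivity experiments.
#'
#' @param dag a `gango_dag` from [generate_dag()].
#' @param n number of samples (>= 10).
#' @param noise a `gango_noise` from [noise_spec()].
#' @param seed integer seed.
#' @param ar AR(1) coefficient for optional temporal coloring; default 0
#'   (i.i.d. rows).
#' @return An `n x p` numeric matrix with parcel-id column names and the
#'   generating DAG attached as attribute `"dag"`.
#' @export
simulate_lingam <- function(dag, n, noise = noise_spec("exponential"),
                            seed = 1L, ar = 0) {
  stopifnot(inherits(dag, "gango_dag"))
  if (n < 10) stopf("n must be >= 10, got %s", n)
  if (!inherits(noise, "gango_noise")) stopf("noise must be a gango_noise")
  p <- dag$p
  with_seed(seed, {
    e <- matrix(draw_noise(noise, n * p), n, p)
    if (ar != 0) {
      e <- apply(e, 2, function(col) as.numeric(stats::filter(
        col, ar, method = "recursive")))
    }
    x <- matrix(0, n, p)
    parents <- split(seq_len(nrow(dag$edges)), dag$edges[, 2])
    for (v in dag$order) {
      x[, v] <- e[, v]
      rows <- parents[[as.character(v)]]
      if (!is.null(rows)) {
        pa <- dag$edges[rows, 1]
        x[, v] <- x[, v] + x[, pa, drop = FALSE] %*% dag$weights[rows]
      }
    }
    colnames(x) <- dag$nodes
    attr(x, "dag") <- dag
    x
  })
}

#' Draw Gaussian surrogate time series
#'
#' i.i.d. standard normal series of the same dimensions as an observed data
#' matrix; the reference distribution for the non-Gaussianity gate.
#'
#' @param p number of series (columns).
#' @param n samples per series.
#' @param seed integer seed.
#' @return An `n x p` numeric matrix.
#' @export
gaussian_surrogates <- function(p, n, seed = 1L) {
  stopifnot(p >= 1, n >= 1)
  with_seed(seed, matrix(rnorm(n * p), n, p))
}

#' Assign nodes to modules at random
#'
#' A fixture partition standing in for a published resting-state network
#' atlas: every module is non-empty and sizes are as equal as possible,
#' with the assignment shuffled uniformly at random.
#'
#' @param p node count.
#' @param n_modules number of modules (<= p); default 12, the usual
#'   resting-state network count.
#' @param seed integer seed.
#' @return Character vector of length `p` with module labels `"M01"`...,
#'   named by parcel id.
#' @export
generate_partition <- function(p, n_modules = 12L, seed = 1L) {
  if (n_modules > p) stopf("n_modules (%s) exceeds p (%s)", n_modules, p)
  labels <- sprintf("M%02d", seq_len(n_modules))
  base <- rep(labels, length.out = p)
  with_seed(seed, {
    out <- base[sample.int(p)]
    names(out) <- node_names(p)
    out
  })
}
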