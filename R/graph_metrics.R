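#' Local (weighted) density of one node
#'
#' The mean connection strength of node `i` to the other `N - 1` nodes:
#' `WD_loc(i) = sum_j c_ij / (N - 1)`. For binary networks the sum is the node
#' degree `k_i` and the value is `k_i / (N - 1)`.
#'
#' @param net A `thresholded_network`.
#' @param node Node index; if omitted, a vector over all nodes is returned.
#' @return Numeric value (or vector) in `[0, 1]` for weights <= 1.
#' @export
local_density <- function(net, node = NULL) {
  n <- nrow(net$weights)
  if (n < 2) abort("network must have at least 2 nodes")
  vals <- rowSums(net$weights) / (n - 1)
  if (is.null(node)) return(vals)
  if (node < 1 || node > n) abort("node index out of range")
  vals[node]
}

#' Global (weighted) density
#'
#' Mean of the local densities over all nodes; for binary networks this is the
#' realized fraction of possible edges and `D * (N - 1)` is the average node
#' degree. Represents the network's overall wiring cost.
#'
#' @param net A `thresholded_network`.
#' @return Numeric scalar.
#' @export
global_density <- function(net) {
  mean(local_density(net))
}

#' Binary global clustering coefficient
#'
#' Average over nodes of the local clustering coefficient
#' `C_loc(i) = (number of closed triangles through i) / (k_i (k_i - 1) / 2)`,
#' equivalently `sum_{j,h} a_ij a_ih a_jh / (k_i (k_i - 1))` on the 0/1
#' adjacency; nodes with degree < 2 contribute 0.
#'
#' @param net A binary `thresholded_network`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  if (!isTRUE(net$binary)) {
    abort("clustering coefficient is defined here for binary networks; binarize() first")
  }
  a <- net$weights
  k <- rowSums(a)
  tri2 <- diag(a %*% a %*% a) # = 2 * triangles through i
  c_loc <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  mean(c_loc)
}

# All-pairs shortest path lengths of a binary graph by simultaneous
# breadth-first search (boolean matrix powers). Unreachable pairs stay Inf.
binary_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- (a > 0) * 1
  step <- 1L
  repeat {
    new <- reach > 0 & !is.finite(d)
    if (!any(new)) break
    d[new] <- step
    if (step >= n) break
    reach <- (reach %*% (a > 0)) > 0
    step <- step + 1L
  }
  d
}

#' Binary global efficiency
#'
#' Mean inverse shortest-path length:
#' `E = (1/N) * sum_i [ sum_{j != i} 1/d_ij ] / (N - 1)`, with `1/d = 0` for
#' disconnected pairs. Path lengths come from breadth-first search on the
#' binary adjacency.
#'
#' @param net A binary `thresholded_network`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  if (!isTRUE(net$binary)) {
    abort("global efficiency is defined here for binary networks; binarize() first")
  }
  d <- binary_distances(net$weights)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  mean(rowSums(inv) / (n - 1))
}

#' All global metrics of one network
#'
#' @param net A `thresholded_network`; clustering and efficiency are computed
#'   only when the network is binary.
#' @return One-row tibble with `D`, `avg_degree` (binary only), `C`, `E`,
#'   `weighted`, `n_nodes`.
#' @export
network_metrics <- function(net) {
  n <- nrow(net$weights)
  d <- global_density(net)
  tibble(
    D = d,
    avg_degree = if (isTRUE(net$binary)) d * (n - 1) else NA_real_,
    C = if (isTRUE(net$binary)) clustering_coefficient(net) else NA_real_,
    E = if (isTRUE(net$binary)) global_efficiency(net) else NA_real_,
    weighted = !isTRUE(net$binary),
    n_nodes = n
  )
}

#' Cost-integrated network metrics
#'
#' Binarized cost-thresholded networks are computed for every cost in the
#' grid and the clustering coefficient and global efficiency (and density) are
#' summed across the grid. Summing across cost levels removes the dependence
#' of any single cost choice while preserving subject and state contrasts.
#'
#' @param cm A `connection_matrix`.
#' @param cost_grid Numeric vector of costs in (0, 1]; default 0.10-0.85 in
#'   steps of 0.05.
#' @return One-row tibble with summed `D`, `C`, `E` and the grid size, plus a
#'   `per_cost` list-column with the per-cost metrics.
#' @export
cost_integrated_metrics <- function(cm, cost_grid = seq(0.10, 0.85, by = 0.05)) {
  if (length(cost_grid) == 0 || any(cost_grid <= 0 | cost_grid > 1)) {
    abort("cost grid must be non-empty and lie in (0, 1]")
  }
  per <- purrr::map_dfr(cost_grid, function(cost) {
    net <- binarize(threshold_cost(cm, cost))
    out <- network_metrics(net)
    out$cost <- cost
    out
  })
  tibble(
    D = sum(per$D), C = sum(per$C), E = sum(per$E),
    n_costs = length(cost_grid), per_cost = list(per)
  )
}
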