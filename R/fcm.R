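# Fuzzy c-means clustering, used to seed the Gaussian premise membership
# functions of the neuro-fuzzy correlation model.

#' Fuzzy c-means clustering
#'
#' Minimizes the fuzzy distortion `J = sum_ij u_ij^m ||x_i - v_j||^2` by
#' alternating exact center and membership updates. The objective is
#' recorded after each center update and is non-increasing by construction.
#' If centers collapse (duplicate data can merge two clusters), the run is
#' restarted from a fresh random membership matrix, at most 5 times.
#'
#' @param x Numeric data matrix, `n x d`.
#' @param c Number of clusters, `1 <= c < n`.
#' @param m Fuzzifier, > 1 (default 2): larger values give softer
#'   memberships.
#' @param tol Convergence tolerance on the objective decrease, default 1e-5.
#' @param max_iter Iteration cap, default 200.
#' @param seed Integer seed for the random membership initialization.
#' @return An object of class `fcm_result`: `centers` (`c x d`),
#'   `memberships` (`n x c`, rows sum to 1), `fuzzifier`,
#'   `objective_history`.
#' @export
#' @examples
#' fit <- fcm_cluster(matrix(rnorm(60), 30), c = 2, seed = 1)
#' range(rowSums(fit$memberships))
fcm_cluster <- function(x, c, m = 2, tol = 1e-5, max_iter = 200, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(is.numeric(c), length(c) == 1L, c >= 1, m > 1, max_iter >= 1)
  c <- as.integer(c)
  if (n <= c) {
    stop_respmark("need more data points than clusters", "invalid_parameter")
  }

  for (restart in 1:5) {
    u <- with_seed(derive_seed(seed, paste0("fcm-init-", restart)), {
      u0 <- matrix(stats::runif(n * c), n, c)
      u0 / rowSums(u0)
    })
    obj <- numeric(0)
    collapsed <- FALSE
    centers <- NULL
    for (iter in seq_len(max_iter)) {
      um <- u^m
      centers <- crossprod(um, x) / colSums(um)
      if (anyNA(centers) || !all(is.finite(centers))) {
        collapsed <- TRUE
        break
      }
      # squared distances point-to-center, n x c
      d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      d2 <- pmax(d2, 0)
      obj <- c(obj, sum(um * d2))
      if (c > 1 && min(stats::dist(centers)) < 1e-9) {
        collapsed <- TRUE
        break
      }
      # membership update; points sitting exactly on a center get a crisp row
      zero <- d2 < 1e-300
      inv <- (1 / pmax(d2, 1e-300))^(1 / (m - 1))
      u_new <- inv / rowSums(inv)
      hit <- rowSums(zero) > 0
      if (any(hit)) {
        u_new[hit, ] <- zero[hit, , drop = FALSE] /
          rowSums(zero[hit, , drop = FALSE])
      }
      u <- u_new
      if (iter > 1 && abs(obj[iter - 1] - obj[iter]) < tol) break
    }
    if (!collapsed) {
      return(structure(
        list(centers = centers, memberships = u, fuzzifier = m,
             objective_history = obj),
        class = "fcm_result"
      ))
    }
    message("fcm_cluster: cluster collapse, restarting (", restart, "/5)")
  }
  stop_respmark("fuzzy c-means failed to separate clusters after 5 restarts",
                "degenerate_input")
}
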