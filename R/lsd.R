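#' Strict-clock least-squares dating
#'
#' Estimates a global substitution rate and internal-node times from a
#' rooted phylogram and tip dates by minimising the weighted least-squares
#' objective
#' \deqn{\sum_i w_i (b_i - r (\tau_{c(i)} - \tau_{p(i)}))^2}
#' over the rate `r > 0` and forward-time node positions `tau`, with tip
#' times fixed at their sampling dates and the temporal-precedence
#' constraint `tau_child >= tau_parent` on every branch. The weights
#' `w_i = 1 / (b_i + c/s)` approximate the inverse variance of a branch
#' length estimated from `s` sites (Poisson noise plus a small-sample
#' offset `c`). The problem is solved by alternating a closed-form rate
#' update with an active-set quadratic program for the node times
#' (branches whose precedence constraint binds are contracted into groups;
#' Lagrange multipliers decide when to release them); the rate is kept
#' positive by projection.
#'
#' @param tree A rooted `phylo` with branch lengths in subs/site.
#' @param dates Tip-date tibble with at least two distinct ages.
#' @param site_count Number of sites `s` behind the branch lengths.
#' @param variance_offset_c Weight offset `c` (default 10).
#' @param tol Relative objective-improvement convergence tolerance.
#' @param max_iter Maximum number of alternating iterations.
#' @return A list with components `estimate` (a [rate_estimate()]) and
#'   `dated_tree` (a `dated_tree`: the topology with estimated node ages in
#'   years BP and branch lengths in years).
#' @export
lsd_estimate <- function(tree, dates, site_count = 15000,
                         variance_offset_c = 10, tol = 1e-12,
                         max_iter = 200L) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) rlang::abort("`tree` must be rooted.")
  tree <- stats::reorder(tree, "cladewise")
  dates <- tip_dates(dates)
  n <- ape::Ntip(tree)
  n_all <- n + tree$Nnode
  ages <- date_vector(dates, tree$tip.label)
  if (length(unique(ages)) < 2) {
    rlang::abort("all tip dates are equal: no temporal spread to date against.")
  }
  edge <- tree$edge
  b <- tree$edge.length
  w <- 1 / (b + variance_offset_c / site_count)

  is_tip <- c(rep(TRUE, n), rep(FALSE, tree$Nnode))

  # feasible start: each internal node slightly older than all its children
  span <- diff(range(-ages))
  delta <- span * 1e-3
  tau <- rep(Inf, n_all)
  tau[seq_len(n)] <- -ages
  for (e in rev(seq_len(nrow(edge)))) {   # children before parents
    p <- edge[e, 1]; ch <- edge[e, 2]
    tau[p] <- min(tau[p], tau[ch] - delta)
  }

  r <- init_rate(tree, dates)
  obj <- lsd_objective(b, w, r, tau, edge)
  active <- rep(FALSE, nrow(edge))
  for (iter in seq_len(max_iter)) {
    step <- lsd_time_step(tau, r, b, w, edge, is_tip, active)
    tau <- step$tau
    active <- step$active
    dtau <- tau[edge[, 2]] - tau[edge[, 1]]
    denom <- sum(w * dtau^2)
    if (denom > 0) r <- max(sum(w * b * dtau) / denom, 1e-15)
    obj_new <- lsd_objective(b, w, r, tau, edge)
    if (obj - obj_new <= tol * max(obj, 1e-300)) {
      obj <- obj_new
      break
    }
    obj <- obj_new
  }

  ages_est <- -tau
  ages_est[seq_len(n)] <- ages      # exact tip dates
  phy_years <- tree
  phy_years$edge.length <- pmax(ages_est[edge[, 1]] - ages_est[edge[, 2]], 0)
  dated <- structure(
    list(phy = phy_years, ages = ages_est, dates = dates, rate = r),
    class = "dated_tree"
  )
  est <- rate_estimate(
    method = "lsd", rate = r, tmrca_age = ages_est[n + 1L], rss = obj
  )
  list(estimate = est, dated_tree = dated)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf(
    "<dated_tree> %d tips, estimated root age %.6g years BP, rate %.6g subs/site/year\n",
    ape::Ntip(x$phy), x$ages[ape::Ntip(x$phy) + 1L], x$rate
  ))
  invisible(x)
}

lsd_objective <- function(b, w, r, tau, edge) {
  dtau <- tau[edge[, 2]] - tau[edge[, 1]]
  sum(w * (b - r * dtau)^2)
}

init_rate <- function(tree, dates) {
  est <- suppressWarnings(tryCatch(rtt_regression(tree, dates)$rate,
                                   error = function(e) NA_real_))
  if (is.na(est) || est <= 0) 1e-10 else est
}

# one constrained weighted-least-squares solve for the node times at fixed
# rate, in substitution-scaled time theta = r * tau (anchors theta_tip =
# r * tau_tip; constraints theta_child >= theta_parent); the active set is
# warm-started across calls
lsd_time_step <- function(tau, r, b, w, edge, is_tip, active) {
  n_edge <- nrow(edge)
  theta <- r * tau
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 4L * n_edge + 20L) break
    theta_star <- lsd_solve_groups(theta, b, w, edge, is_tip, active)
    d_cur <- theta[edge[, 2]] - theta[edge[, 1]]
    d_new <- theta_star[edge[, 2]] - theta_star[edge[, 1]]
    viol <- which(!active & d_new < -1e-12 * (1 + abs(d_new)))
    if (length(viol) == 0) {
      theta <- theta_star
      lam <- lsd_multipliers(theta, b, w, edge, is_tip, active)
      neg <- which(active)[lam < -1e-9]
      if (length(neg) == 0) break
      worst <- which(active)[which.min(lam)]
      active[worst] <- FALSE
    } else {
      alpha <- pmax(d_cur[viol], 0) / (d_cur[viol] - d_new[viol])
      alpha[!is.finite(alpha)] <- 0
      k <- which.min(alpha)
      a <- min(max(alpha[k], 0), 1)
      theta <- theta + a * (theta_star - theta)
      active[viol[k]] <- TRUE
      # numerical cleanup: keep the activated pair exactly equal
      theta[edge[viol[k], 2]] <- theta[edge[viol[k], 1]]
    }
  }
  list(tau = theta / r, active = active)
}

# solve the equality-constrained problem: nodes joined by active edges are
# contracted into groups; groups containing a tip are anchored at its value
lsd_solve_groups <- function(theta, b, w, edge, is_tip, active) {
  n_all <- length(theta)
  group <- seq_len(n_all)
  find <- function(i) {
    while (group[i] != i) {
      group[i] <<- group[group[i]]
      i <- group[i]
    }
    i
  }
  for (e in which(active)) {
    a <- find(edge[e, 1]); c2 <- find(edge[e, 2])
    if (a != c2) group[c2] <- a
  }
  gid <- vapply(seq_len(n_all), find, integer(1))
  gidx <- match(gid, unique(gid))          # compact group index 1..k
  k <- max(gidx)
  anchor <- rep(NA_real_, k)
  anchor[gidx[is_tip]] <- theta[is_tip]
  free <- which(is.na(anchor))
  vals <- anchor
  if (length(free) > 0) {
    fmap <- integer(k)
    fmap[free] <- seq_along(free)
    A <- matrix(0, length(free), length(free))
    rhs <- numeric(length(free))
    gp_all <- gidx[edge[, 1]]
    gc_all <- gidx[edge[, 2]]
    for (e in seq_len(nrow(edge))) {
      gp <- gp_all[e]; gc <- gc_all[e]
      if (gp == gc) next
      we <- w[e]; be <- b[e]
      ip <- fmap[gp]; ic <- fmap[gc]
      if (ic > 0L) {
        A[ic, ic] <- A[ic, ic] + we
        rhs[ic] <- rhs[ic] + we * be
        if (ip > 0L) A[ic, ip] <- A[ic, ip] - we
        else rhs[ic] <- rhs[ic] + we * anchor[gp]
      }
      if (ip > 0L) {
        A[ip, ip] <- A[ip, ip] + we
        rhs[ip] <- rhs[ip] - we * be
        if (ic > 0L) A[ip, ic] <- A[ip, ic] - we
        else rhs[ip] <- rhs[ip] + we * anchor[gc]
      }
    }
    vals[free] <- solve(A, rhs)
  }
  out <- vals[gidx]
  out[is_tip] <- theta[is_tip]
  out
}

# Lagrange multipliers of the active precedence constraints at a solution:
# sum the objective gradient over the child-side component of each active
# edge (or minus the parent-side sum when the child side holds the anchor)
lsd_multipliers <- function(theta, b, w, edge, is_tip, active) {
  act_idx <- which(active)
  if (length(act_idx) == 0) return(numeric(0))
  n_all <- length(theta)
  grad <- numeric(n_all)
  d <- theta[edge[, 2]] - theta[edge[, 1]]
  t2 <- 2 * w * (d - b)
  for (e in seq_len(nrow(edge))) {
    grad[edge[e, 2]] <- grad[edge[e, 2]] + t2[e]
    grad[edge[e, 1]] <- grad[edge[e, 1]] - t2[e]
  }
  adj <- vector("list", n_all)
  for (e in act_idx) {
    a <- edge[e, 1]; c2 <- edge[e, 2]
    adj[[a]] <- c(adj[[a]], e)
    adj[[c2]] <- c(adj[[c2]], e)
  }
  component <- function(start, skip_edge) {
    seen <- integer(0)
    stack <- start
    while (length(stack) > 0) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      for (e in adj[[v]]) {
        if (e == skip_edge) next
        nxt <- if (edge[e, 1] == v) edge[e, 2] else edge[e, 1]
        if (!(nxt %in% seen)) stack <- c(stack, nxt)
      }
    }
    seen
  }
  vapply(act_idx, function(e) {
    s_c <- component(edge[e, 2], e)
    if (!any(is_tip[s_c])) {
      sum(grad[s_c])
    } else {
      s_p <- component(edge[e, 1], e)
      if (any(is_tip[s_p])) return(0)
      -sum(grad[s_p[!is_tip[s_p]]])
    }
  }, numeric(1))
}
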