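# Mixed-integer model construction. The model is held as an abstract sparse
# description (objective vector, triplet constraint matrix, row/variable
# bounds, integrality) so that any MILP engine honoring that contract can be
# plugged in behind milp_solve().

#' Solve options
#'
#' @param time_limit_s wall-clock limit per solve, seconds.
#' @param mip_gap relative optimality gap; `NULL` inherits the instance
#'   config's `mip_gap`.
#' @param linking_mode `"tight"` (per-pair `Y <= Z`, `Z <= X`; default) or
#'   `"big_m"` (the aggregated big-M linking inequalities
#'   `sum_p Y <= M Z` and `sum_d Z <= M X`). Both describe the same feasible
#'   set of integer points; the tight form has the stronger LP relaxation.
#' @param threads solver threads (the HiGHS backend is deterministic at 1).
#' @param verbose print solver log.
#' @return list of class `solve_options`.
#' @export
solve_options <- function(time_limit_s = 120, mip_gap = NULL,
                          linking_mode = c("tight", "big_m"),
                          threads = 1L, verbose = FALSE) {
  linking_mode <- match.arg(linking_mode)
  stopifnot(time_limit_s > 0, is.null(mip_gap) || mip_gap >= 0)
  structure(list(time_limit_s = time_limit_s, mip_gap = mip_gap,
                 linking_mode = linking_mode, threads = as.integer(threads),
                 verbose = isTRUE(verbose)),
            class = "solve_options")
}

# per-group initial active segment: the one containing the quality function's
# baseline anchor (clipped to the domain), else the topmost segment
initial_segments <- function(inst) {
  vapply(as.character(inst$groups$id), function(id) {
    qf <- inst$quality[[id]]
    anchor <- attr(qf, "baseline_nl")
    hi <- max(qf$nl_hi)
    if (is.null(anchor)) return(qf_segment_index(qf, hi))
    qf_segment_index(qf, min(anchor, hi))
  }, integer(1))
}

# active_segments: integer vector (segment index per group, in group order)
active_segment_table <- function(inst, active_segments) {
  do.call(rbind, lapply(seq_len(nrow(inst$groups)), function(j) {
    qf <- inst$quality[[as.character(inst$groups$id[j])]]
    qf[active_segments[j], c("nl_lo", "nl_hi", "slope", "intercept")]
  }))
}

#' Build the facility-location MIP for an instance
#'
#' Creates binaries `X_q` (site open), `Z_{q,d}` (group offered at site) and
#' `Y_{p,q,d}` (zip assigned to site for group) — the latter only for pairs
#' within the group's maximum travel time, which enforces
#' `Y_{p,q,d} TT_{p,q} <= maxt_d` by variable-domain restriction. Constraints:
#' assignment completeness `sum_q Y_{p,q,d} = 1`, assignment/offering/open
#' linking (tight or big-M), co-location equality for configured pairs, and
#' minimum-utilization rows per the configured mode (`conditional` adds a
#' facility-present binary `W_{q,f}` with semicontinuous usage; `literal`
#' forces every facility minimum at every open site). The objective maximizes
#' `sum_d [EQ NP_d (a_d NL_d + b_d) - rt ET NV_d sum_{p,q} NP^D_{p,d}
#' Y_{p,q,d} TT_{p,q}/60]` with `NL_d = sum_q Z_{q,d}` and the active
#' linear segment `(a_d, b_d)` of each group's quality function.
#'
#' @param inst a `hosp_instance`.
#' @param active_segments integer vector of segment indices per group
#'   (default: segment containing each quality function's baseline anchor).
#' @param linking_mode `"tight"` or `"big_m"`.
#' @return list of class `hosp_model` (objective, triplets, bounds, variable
#'   maps, constant term).
#' @export
build_model <- function(inst, active_segments = NULL,
                        linking_mode = c("tight", "big_m")) {
  linking_mode <- match.arg(linking_mode)
  P <- nrow(inst$zips); Q <- nrow(inst$sites); D <- nrow(inst$groups)
  if (is.null(active_segments)) active_segments <- initial_segments(inst)
  seg <- active_segment_table(inst, active_segments)
  cf <- inst$config

  # allowed (zip, site) pairs per group; fail early on uncovered demand
  ylist <- vector("list", D)
  uncovered <- list()
  for (j in seq_len(D)) {
    ok <- which(inst$travel <= inst$groups$max_travel_min[j], arr.ind = TRUE)
    cov <- tabulate(ok[, 1], nbins = P)
    if (any(cov == 0))
      uncovered[[length(uncovered) + 1L]] <-
        data.frame(group_id = inst$groups$id[j],
                   zip_id = inst$zips$id[cov == 0])
    ylist[[j]] <- data.frame(p = ok[, 1], q = ok[, 2],
                             j = rep(j, nrow(ok)))
  }
  if (length(uncovered)) {
    bad <- do.call(rbind, uncovered)
    stop(structure(class = c("hosp_uncovered_demand", "error", "condition"),
                   list(message = paste0(
                     "no candidate site within the maximum travel time for ",
                     nrow(bad), " zip-group pair(s), e.g. zip ", bad$zip_id[1],
                     " group ", bad$group_id[1]),
                     call = sys.call(), uncovered = bad)))
  }
  ymap <- do.call(rbind, ylist)
  nY <- nrow(ymap)

  x_idx <- seq_len(Q)
  z_idx <- matrix(Q + seq_len(Q * D), Q, D)
  y_off <- Q + Q * D
  ymap$idx <- y_off + seq_len(nY)
  mu <- cf$min_utilization
  use_w <- cf$utilization_mode == "conditional" && any(mu > 0)
  w_idx <- NULL
  n_var <- y_off + nY
  if (use_w) {
    w_idx <- matrix(n_var + seq_len(Q * 3), Q, 3,
                    dimnames = list(NULL, facility_types()))
    n_var <- n_var + Q * 3
  }

  # objective (maximize)
  obj <- numeric(n_var)
  for (j in seq_len(D))
    obj[z_idx[, j]] <- cf$euros_per_qaly * inst$groups$n_patients[j] *
      seg$slope[j]
  trav_coef <- cf$round_trip_factor * cf$euros_per_travel_hour *
    inst$groups$n_visits[ymap$j] * inst$demand[cbind(ymap$p, ymap$j)] *
    inst$travel[cbind(ymap$p, ymap$q)] / 60
  obj[ymap$idx] <- -trav_coef
  constant <- sum(cf$euros_per_qaly * inst$groups$n_patients * seg$intercept)

  tri_i <- list(); tri_j <- list(); tri_v <- list()
  rlb <- list(); rub <- list()
  nrow_ <- 0L
  add_rows <- function(i, j, v, lo, hi) {
    tri_i[[length(tri_i) + 1L]] <<- i + nrow_
    tri_j[[length(tri_j) + 1L]] <<- j
    tri_v[[length(tri_v) + 1L]] <<- v
    rlb[[length(rlb) + 1L]] <<- lo
    rub[[length(rub) + 1L]] <<- hi
    nrow_ <<- nrow_ + length(lo)
  }

  # assignment completeness: one row per (p, d)
  arow <- (ymap$j - 1L) * P + ymap$p
  arow <- match(arow, sort(unique(arow)))  # dense row ids in (j, p) order
  n_assign <- max(arow)
  add_rows(arow, ymap$idx, rep(1, nY), rep(1, n_assign), rep(1, n_assign))

  if (linking_mode == "tight") {
    # Y - Z <= 0, one row per Y variable
    add_rows(c(seq_len(nY), seq_len(nY)),
             c(ymap$idx, z_idx[cbind(ymap$q, ymap$j)]),
             c(rep(1, nY), rep(-1, nY)),
             rep(-Inf, nY), rep(0, nY))
    # Z - X <= 0, one row per (q, d)
    add_rows(c(seq_len(Q * D), seq_len(Q * D)),
             c(as.vector(z_idx), rep(x_idx, D)),
             c(rep(1, Q * D), rep(-1, Q * D)),
             rep(-Inf, Q * D), rep(0, Q * D))
  } else {
    # sum_p Y - M Z <= 0, one row per (q, d) with any Y
    qd <- (ymap$j - 1L) * Q + ymap$q
    qd_u <- sort(unique(qd))
    r <- match(qd, qd_u)
    nqd <- length(qd_u)
    add_rows(c(r, seq_len(nqd)),
             c(ymap$idx, as.vector(z_idx)[qd_u]),
             c(rep(1, nY), rep(-cf$big_m, nqd)),
             rep(-Inf, nqd), rep(0, nqd))
    # sum_d Z - M X <= 0, one row per q
    add_rows(c(rep(seq_len(Q), D), seq_len(Q)),
             c(as.vector(z_idx), x_idx),
             c(rep(1, Q * D), rep(-cf$big_m, Q)),
             rep(-Inf, Q), rep(0, Q))
  }

  # co-location: Z_{q,g1} - Z_{q,g2} = 0
  for (i in seq_len(nrow(inst$colocate))) {
    j1 <- match(inst$colocate[i, 1], inst$groups$id)
    j2 <- match(inst$colocate[i, 2], inst$groups$id)
    add_rows(c(seq_len(Q), seq_len(Q)),
             c(z_idx[, j1], z_idx[, j2]),
             c(rep(1, Q), rep(-1, Q)),
             rep(0, Q), rep(0, Q))
  }

  # utilization
  if (any(mu > 0)) {
    w_pat <- inst$demand[cbind(ymap$p, ymap$j)]  # patients on each Y arc
    for (f in facility_types()) {
      if (mu[[f]] <= 0) next
      coefs <- w_pat * inst$usage[ymap$j, f]
      keep <- coefs > 0
      if (!any(keep)) next
      qk <- ymap$q[keep]; idxk <- ymap$idx[keep]; ck <- coefs[keep]
      qs <- sort(unique(qk))
      r <- match(qk, qs); nq <- length(qs)
      cap <- sum(ck)
      if (cf$utilization_mode == "conditional") {
        # usage - cap * W <= 0  (facility present whenever used)
        add_rows(c(r, seq_len(nq)), c(idxk, w_idx[qs, f]),
                 c(ck, rep(-cap, nq)), rep(-Inf, nq), rep(0, nq))
        # usage - minu * W >= 0  (present implies efficiently used)
        add_rows(c(r, seq_len(nq)), c(idxk, w_idx[qs, f]),
                 c(ck, rep(-mu[[f]], nq)), rep(0, nq), rep(Inf, nq))
      } else {
        # literal: usage - minu * X >= 0 at every site (row index = site)
        add_rows(c(qk, seq_len(Q)), c(idxk, x_idx),
                 c(ck, rep(-mu[[f]], Q)), rep(0, Q), rep(Inf, Q))
      }
    }
    if (cf$utilization_mode == "literal") {
      # facilities with minima but no usable patient supply make any open
      # site infeasible only through the rows above; facilities nobody uses
      # still bind literally: minu_f X_q <= 0 forces X_q = 0
      for (f in facility_types()) {
        if (mu[[f]] <= 0) next
        coefs <- w_pat * inst$usage[ymap$j, f]
        if (any(coefs > 0)) next
        add_rows(seq_len(Q), x_idx, rep(-mu[[f]], Q),
                 rep(0, Q), rep(Inf, Q))
      }
    }
  }

  structure(list(
    n_var = n_var, obj = obj, constant = constant, maximize = TRUE,
    ai = unlist(tri_i), aj = unlist(tri_j), av = unlist(tri_v),
    rlb = unlist(rlb), rub = unlist(rub),
    lb = rep(0, n_var), ub = rep(1, n_var),
    integrality = rep(1L, n_var),
    x_idx = x_idx, z_idx = z_idx, ymap = ymap, w_idx = w_idx,
    n_rows = nrow_, linking_mode = linking_mode,
    active_segments = active_segments),
    class = "hosp_model")
}

#' @export
print.hosp_model <- function(x, ...) {
  cat(sprintf("MIP model: %d binaries (%d X, %d Z, %d Y%s), %d rows, %d nnz, %s linking\n",
              x$n_var, length(x$x_idx), length(x$z_idx), nrow(x$ymap),
              if (is.null(x$w_idx)) "" else sprintf(", %d W", length(x$w_idx)),
              x$n_rows, length(x$av), x$linking_mode))
  invisible(x)
}
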