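# Exact brute-force reference for small instances. Shares no code with the
# MIP path: offerings are enumerated as bitmasks, assignments either follow
# the closed-form nearest-feasible rule (when no utilization minima couple
# them) or are enumerated outright. Used as the correctness anchor in tests.

#' Enumeration guards for the brute-force oracle
#'
#' @param max_zips,max_sites,max_groups dimension caps.
#' @param max_states cap on enumerated offering/assignment combinations; the
#'   oracle refuses (with a size estimate) rather than run beyond it.
#' @return list of class `oracle_limits`.
#' @export
oracle_limits <- function(max_zips = 8L, max_sites = 6L, max_groups = 3L,
                          max_states = 2e6) {
  stopifnot(max_zips >= 1, max_sites >= 1, max_groups >= 1, max_states >= 1)
  structure(list(max_zips = as.integer(max_zips),
                 max_sites = as.integer(max_sites),
                 max_groups = as.integer(max_groups),
                 max_states = max_states),
            class = "oracle_limits")
}

#' Nearest feasible assignment given fixed offerings
#'
#' Assigns every zip-group pair to the offering site with the smallest drive
#' time among sites within the group's maximum travel time; ties are broken
#' by the lower site index.
#'
#' @param inst a `hosp_instance`.
#' @param offers 0/1 matrix sites x groups.
#' @return integer matrix zips x groups of site indices, or `NULL` with
#'   attribute-free `NA` entries never produced: uncovered pairs raise a
#'   condition of class `hosp_uncovered_demand`.
#' @export
nearest_feasible_assignment <- function(inst, offers) {
  P <- nrow(inst$zips); D <- nrow(inst$groups)
  assign <- matrix(NA_integer_, P, D)
  bad <- list()
  for (j in seq_len(D)) {
    open_q <- which(offers[, j] == 1)
    maxt <- inst$groups$max_travel_min[j]
    for (p in seq_len(P)) {
      tt <- inst$travel[p, open_q]
      ok <- which(tt <= maxt)
      if (!length(ok)) {
        bad[[length(bad) + 1L]] <- data.frame(
          group_id = inst$groups$id[j], zip_id = inst$zips$id[p])
        next
      }
      best <- ok[order(tt[ok], open_q[ok])][1]
      assign[p, j] <- open_q[best]
    }
  }
  if (length(bad)) {
    b <- do.call(rbind, bad)
    stop(structure(class = c("hosp_uncovered_demand", "error", "condition"),
                   list(message = paste0("no offering site within reach for ",
                                         nrow(b), " zip-group pair(s)"),
                        call = sys.call(), uncovered = b)))
  }
  assign
}

# travel euros of a full assignment matrix
oracle_travel <- function(inst, assign) {
  sum(vapply(seq_len(nrow(inst$groups)),
             function(j) compute_travel_eur(inst, assign, j), numeric(1)))
}

# group clusters tied by co-location (site sets must coincide)
colocation_clusters <- function(inst) {
  D <- nrow(inst$groups)
  cl <- seq_len(D)
  for (i in seq_len(nrow(inst$colocate))) {
    j1 <- match(inst$colocate[i, 1], inst$groups$id)
    j2 <- match(inst$colocate[i, 2], inst$groups$id)
    cl[cl == cl[j2]] <- cl[j1]
  }
  match(cl, unique(cl))
}

#' Exact optimum of a small instance by exhaustive enumeration
#'
#' Enumerates per-cluster offering site sets as bitmasks (co-located groups
#' share one mask). Without utilization minima the optimal assignment given
#' offerings is the closed-form nearest-feasible rule and clusters decouple,
#' so each cluster's best mask is found independently. With minima active the
#' joint offering combination is enumerated together with every admissible
#' assignment, subject to the `max_states` guard. Ties are broken toward the
#' lexicographically smallest encoding, making the result deterministic.
#'
#' @param inst a `hosp_instance`.
#' @param limits an [oracle_limits()].
#' @return a `hosp_solution` (status `"optimal"`, gap 0), or one with
#'   `solver_status = "infeasible"` when no admissible configuration exists.
#' @export
enumerate_optimum <- function(inst, limits = oracle_limits()) {
  P <- nrow(inst$zips); Q <- nrow(inst$sites); D <- nrow(inst$groups)
  if (P > limits$max_zips || Q > limits$max_sites || D > limits$max_groups)
    stop("instance exceeds oracle limits (", P, " zips, ", Q, " sites, ",
         D, " groups)", call. = FALSE)
  eq <- inst$config$euros_per_qaly
  mu <- inst$config$min_utilization
  minima <- any(mu > 0)
  masks <- seq_len(2^Q - 1L)
  memb <- t(vapply(masks, function(m) as.logical(bitwAnd(m, 2^(0:(Q - 1)))),
                   logical(Q)))  # mask x site membership
  nl_of_mask <- rowSums(memb)
  clusters <- colocation_clusters(inst)
  n_cl <- max(clusters)

  qual_of <- function(j, nl) evaluate_quality_eur(
    inst$groups[j, ], inst$quality[[as.character(inst$groups$id[j])]], nl, eq)

  if (!minima) {
    # clusters decouple: best mask per cluster via closed-form assignment
    offers <- matrix(0L, Q, D)
    assign <- matrix(NA_integer_, P, D)
    total_quality <- 0
    for (cl in seq_len(n_cl)) {
      js <- which(clusters == cl)
      best_val <- -Inf; best_m <- NA_integer_
      best_assign <- NULL
      for (m in masks) {
        open_q <- which(memb[m, ])
        val <- 0; amat <- matrix(NA_integer_, P, length(js))
        feasible <- TRUE
        for (k in seq_along(js)) {
          j <- js[k]
          maxt <- inst$groups$max_travel_min[j]
          for (p in seq_len(P)) {
            tt <- inst$travel[p, open_q]
            ok <- which(tt <= maxt)
            if (!length(ok)) { feasible <- FALSE; break }
            amat[p, k] <- open_q[ok[order(tt[ok], open_q[ok])][1]]
          }
          if (!feasible) break
          w <- inst$demand[, j]
          tt_sel <- inst$travel[cbind(seq_len(P), amat[, k])]
          travel <- inst$config$round_trip_factor *
            inst$config$euros_per_travel_hour * inst$groups$n_visits[j] *
            sum(w * tt_sel) / 60
          val <- val + qual_of(j, nl_of_mask[m]) - travel
        }
        if (feasible && val > best_val + 1e-12) {
          best_val <- val; best_m <- m; best_assign <- amat
        }
      }
      if (is.na(best_m))
        return(structure(list(solver_status = "infeasible",
                              objective_eur = NA_real_),
                         class = "hosp_solution"))
      offers[memb[best_m, ], js] <- 1L
      assign[, js] <- best_assign
      total_quality <- total_quality + best_val
    }
    open <- rowSums(offers) > 0
    return(hosp_solution(inst, open, offers, assign,
                         status = "optimal", gap = 0))
  }

  # minima active: joint enumeration of cluster masks and assignments
  n_joint <- (2^Q - 1)^n_cl
  if (n_joint > limits$max_states)
    stop("oracle state space too large: ", format(n_joint, big.mark = ","),
         " joint offering combinations exceed max_states", call. = FALSE)
  grid <- do.call(expand.grid, rep(list(masks), n_cl))
  best_obj <- -Inf; best <- NULL
  for (r in seq_len(nrow(grid))) {
    cmask <- as.integer(grid[r, ])
    offers <- matrix(0L, Q, D)
    for (cl in seq_len(n_cl)) offers[memb[cmask[cl], ], clusters == cl] <- 1L
    # allowed site lists per (p, d)
    allowed <- vector("list", P * D)
    feasible <- TRUE
    for (j in seq_len(D)) {
      open_q <- which(offers[, j] == 1)
      maxt <- inst$groups$max_travel_min[j]
      for (p in seq_len(P)) {
        a <- open_q[inst$travel[p, open_q] <= maxt]
        if (!length(a)) { feasible <- FALSE; break }
        allowed[[(j - 1L) * P + p]] <- a
      }
      if (!feasible) break
    }
    if (!feasible) next
    n_comb <- prod(vapply(allowed, length, numeric(1)))
    if (n_comb > limits$max_states)
      stop("oracle state space too large: ", format(n_comb, big.mark = ","),
           " assignment combinations exceed max_states", call. = FALSE)
    combos <- as.matrix(do.call(expand.grid, allowed))  # n_comb x (P*D)
    # travel cost per combo
    cost <- numeric(nrow(combos))
    wcol <- rep(seq_len(D), each = P)
    pcol <- rep(seq_len(P), D)
    for (k in seq_len(ncol(combos))) {
      j <- wcol[k]; p <- pcol[k]
      ck <- inst$config$round_trip_factor * inst$config$euros_per_travel_hour *
        inst$groups$n_visits[j] * inst$demand[p, j] *
        inst$travel[p, combos[, k]] / 60
      cost <- cost + ck
    }
    # utilization feasibility per combo
    feas <- rep(TRUE, nrow(combos))
    open_sites <- which(rowSums(offers) > 0)
    for (f in facility_types()) {
      if (mu[[f]] <= 0) next
      w_f <- inst$demand[cbind(pcol, wcol)] * inst$usage[wcol, f]
      for (q in seq_len(Q)) {
        usage_q <- as.numeric((combos == q) %*% w_f)
        if (inst$config$utilization_mode == "conditional") {
          feas <- feas & (usage_q <= 1e-9 | usage_q >= mu[[f]] - 1e-9)
        } else if (q %in% open_sites) {
          feas <- feas & (usage_q >= mu[[f]] - 1e-9)
        }
      }
    }
    if (!any(feas)) next
    quality <- sum(vapply(seq_len(D), function(j)
      qual_of(j, sum(offers[, j])), numeric(1)))
    idx <- which(feas)
    k_best <- idx[which.min(cost[idx])]
    obj <- quality - cost[k_best]
    if (obj > best_obj + 1e-12) {
      best_obj <- obj
      best <- list(offers = offers,
                   assign = matrix(combos[k_best, ], P, D))
    }
  }
  if (is.null(best))
    return(structure(list(solver_status = "infeasible",
                          objective_eur = NA_real_),
                     class = "hosp_solution"))
  hosp_solution(inst, rowSums(best$offers) > 0, best$offers, best$assign,
                status = "optimal", gap = 0)
}
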