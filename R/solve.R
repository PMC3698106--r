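# Solving an instance: single solve with a fixed active linear segment per
# group, and the outer piecewise-segment refinement loop.

# turn raw variable values into a canonical hosp_solution
extract_solution <- function(inst, model, x, status, gap) {
  Q <- nrow(inst$sites); D <- nrow(inst$groups); P <- nrow(inst$zips)
  open <- x[model$x_idx] > 0.5
  offers <- matrix(as.integer(x[as.vector(model$z_idx)] > 0.5), Q, D)
  assign <- matrix(NA_integer_, P, D)
  yv <- x[model$ymap$idx]
  on_arcs <- model$ymap[yv > 0.5, , drop = FALSE]
  # exactly one arc per (p, d) by the completeness constraint; if numerical
  # slack ever yields two, the first (lowest site index) wins
  ord <- order(on_arcs$j, on_arcs$p, on_arcs$q)
  on_arcs <- on_arcs[ord, ]
  first <- !duplicated(on_arcs[, c("p", "j")])
  assign[cbind(on_arcs$p[first], on_arcs$j[first])] <- on_arcs$q[first]

  # canonical minimal offerings: for groups whose quality function is flat
  # (no volume-outcome relation) the solver's unused offerings are objective-
  # neutral noise; keep only sites actually serving demand. Co-located pairs
  # are left untouched to preserve the shared-site-set constraint.
  tied <- unique(as.vector(inst$colocate))
  for (j in seq_len(D)) {
    gid <- inst$groups$id[j]
    qf <- inst$quality[[as.character(gid)]]
    if (all(qf$slope == 0) && !(gid %in% tied)) {
      used <- sort(unique(assign[, j]))
      offers[, j] <- 0L
      offers[used, j] <- 1L
    }
  }
  open <- rowSums(offers) > 0
  hosp_solution(inst, open, offers, assign, status = status, gap = gap)
}

#' Solve an instance with a fixed linear quality segment per group
#'
#' Builds the MIP via [build_model()] and hands it to the solver backend.
#' The returned solution's quality, travel and objective are recomputed in R
#' from the variable values (never taken from the solver), using the full
#' piecewise quality functions, and always pass [validate_solution()].
#'
#' @param inst a `hosp_instance`.
#' @param options a [solve_options()].
#' @param active_segments optional integer vector of active segment indices
#'   per group; default as in [build_model()].
#' @return a `hosp_solution`. On solver infeasibility the returned object has
#'   `solver_status = "infeasible"` and no assignment. Uncovered zip-group
#'   pairs are detected before any solve and raised as a condition of class
#'   `hosp_uncovered_demand`.
#' @export
solve_instance <- function(inst, options = solve_options(),
                           active_segments = NULL) {
  model <- build_model(inst, active_segments = active_segments,
                       linking_mode = options$linking_mode)
  gap <- if (is.null(options$mip_gap)) inst$config$mip_gap else options$mip_gap
  res <- milp_solve(model, time_limit_s = options$time_limit_s,
                    mip_gap = gap, verbose = options$verbose)
  if (res$status %in% c("infeasible", "error") || is.null(res$x)) {
    return(structure(list(open = NULL, offers = NULL, assign = NULL,
                          n_locations = NULL, quality_eur = NULL,
                          travel_eur = NULL, objective_eur = NA_real_,
                          solver_status = res$status,
                          gap = NA_real_, message = res$message),
                     class = "hosp_solution"))
  }
  sol <- extract_solution(inst, model, res$x, res$status, res$gap)
  attr(sol, "model_size") <- c(variables = model$n_var, rows = model$n_rows)
  attr(sol, "active_segments") <- model$active_segments
  sol
}

#' Solve with piecewise-segment refinement
#'
#' The quality functions are piecewise linear, but each solve uses one linear
#' segment per group. The refinement loop starts from the segment containing
#' each function's baseline anchor, solves, and checks whether each group's
#' optimal location count lies inside its active segment's validity interval;
#' if not, the segment containing the observed count is activated and the
#' model re-solved. The loop stops at a fixed point, on a detected cycle, or
#' at the iteration cap, returning the visited solution with the best true
#' piecewise objective (solution objectives are always evaluated on the full
#' piecewise functions, so iterates are comparable).
#'
#' @param inst a `hosp_instance`.
#' @param options a [solve_options()].
#' @return a `hosp_solution` with attributes `refinement_trace` (data frame
#'   of iteration, active segments, objective) and `converged` (logical;
#'   `FALSE` when stopped by cycle or cap).
#' @export
solve_with_refinement <- function(inst, options = solve_options()) {
  active <- initial_segments(inst)
  cap <- inst$config$max_refinement_iters
  visited <- character(0)
  trace <- list(); sols <- list()
  converged <- FALSE
  for (it in seq_len(cap)) {
    sig <- paste(active, collapse = ",")
    visited <- c(visited, sig)
    sol <- solve_instance(inst, options, active_segments = active)
    if (sol$solver_status %in% c("infeasible", "error")) {
      attr(sol, "refinement_trace") <-
        do.call(rbind, trace)
      attr(sol, "converged") <- FALSE
      return(sol)
    }
    trace[[it]] <- data.frame(iteration = it, segments = sig,
                              objective_eur = sol$objective_eur)
    sols[[it]] <- sol
    nl <- sol$n_locations
    nxt <- vapply(seq_along(nl), function(j) {
      qf <- inst$quality[[as.character(inst$groups$id[j])]]
      qf_segment_index(qf, nl[j])
    }, integer(1))
    if (all(nxt == active)) { converged <- TRUE; break }
    if (paste(nxt, collapse = ",") %in% visited) break  # cycle detected
    active <- nxt
  }
  tr <- do.call(rbind, trace)
  # at a fixed point the last iterate is the answer; on cycle/cap fall back
  # to the visited solution with the best true piecewise objective
  best <- if (converged) length(sols) else which.max(tr$objective_eur)
  out <- sols[[best]]
  attr(out, "refinement_trace") <- tr
  attr(out, "converged") <- converged
  out
}
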