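#' Build a least-cost ration linear program
#'
#' Encodes the standard least-cost diet LP: choose dry-matter amounts
#' `x_f >= 0` for each feed minimizing total cost
#' `sum_f cost_f * x_f`, subject to nutrient supply
#' `sum_f comp[f, n] * x_f >= min_n` (and `<= max_n` where a maximum is
#' set), a dry-matter-intake window `DMI_min <= sum_f x_f <= DMI_max`, and
#' per-feed bounds `min_inclusion <= x_f <= min(max_inclusion, available)`.
#'
#' @param feeds data.frame with columns `name`, `cost` (currency/kg DM),
#'   one column per nutrient (amount per kg DM), and optional
#'   `min_inclusion`, `max_inclusion`, `available` (kg DM/d).
#' @param requirements list with `nutrients` — a data.frame with columns
#'   `nutrient`, `min` and optional `max` (amount/d) — and optional
#'   scalars `dmi_min`, `dmi_max` (kg DM/d).
#' @return an object of class `ration_problem`: objective vector,
#'   inequality blocks, and names.
#' @export
build_ration_problem <- function(feeds, requirements) {
  stopifnot(is.data.frame(feeds), nrow(feeds) >= 1,
            is.data.frame(requirements$nutrients),
            nrow(requirements$nutrients) >= 1)
  req <- requirements$nutrients
  nutr <- as.character(req$nutrient)
  missing_cols <- setdiff(nutr, names(feeds))
  if (length(missing_cols))
    stop("nutrient(s) absent from the feed library: ",
         paste(missing_cols, collapse = ", "))
  comp <- t(as.matrix(feeds[, nutr, drop = FALSE]))  # nutrients x feeds
  dimnames(comp) <- list(nutr, feeds$name)
  if (any(comp < 0)) stop("negative composition value in feed library")
  zero_rows <- rownames(comp)[rowSums(comp) == 0 & req$min > 0]
  if (length(zero_rows))
    stop("nutrient(s) supplied by no feed: ", paste(zero_rows, collapse = ", "))

  nf <- nrow(feeds)
  # >= block: nutrient minima, DMI_min, per-feed minima
  A_ge <- comp
  b_ge <- req$min
  if (!is.null(requirements$dmi_min)) {
    A_ge <- rbind(A_ge, DMI = rep(1, nf))
    b_ge <- c(b_ge, requirements$dmi_min)
  }
  # <= block: nutrient maxima, DMI_max, per-feed upper bounds
  A_le <- NULL; b_le <- NULL
  if ("max" %in% names(req)) {
    has_max <- is.finite(req$max)
    if (any(has_max)) {
      A_le <- comp[has_max, , drop = FALSE]
      b_le <- req$max[has_max]
    }
  }
  if (!is.null(requirements$dmi_max)) {
    A_le <- rbind(A_le, DMI = rep(1, nf))
    b_le <- c(b_le, requirements$dmi_max)
  }
  upper <- rep(Inf, nf)
  if ("max_inclusion" %in% names(feeds))
    upper <- pmin(upper, ifelse(is.na(feeds$max_inclusion), Inf,
                                feeds$max_inclusion))
  if ("available" %in% names(feeds))
    upper <- pmin(upper, ifelse(is.na(feeds$available), Inf, feeds$available))
  fin <- is.finite(upper)
  if (any(fin)) {
    up_block <- diag(nf)[fin, , drop = FALSE]
    rownames(up_block) <- paste0("ub_", feeds$name[fin])
    A_le <- rbind(A_le, up_block)
    b_le <- c(b_le, upper[fin])
  }
  lower <- if ("min_inclusion" %in% names(feeds))
    ifelse(is.na(feeds$min_inclusion), 0, feeds$min_inclusion) else rep(0, nf)
  if (any(lower < 0)) stop("min_inclusion must be >= 0")
  pos <- lower > 0
  if (any(pos)) {
    lo_block <- diag(nf)[pos, , drop = FALSE]
    rownames(lo_block) <- paste0("lb_", feeds$name[pos])
    A_ge <- rbind(A_ge, lo_block)
    b_ge <- c(b_ge, lower[pos])
  }

  structure(list(cost = feeds$cost, A_ge = A_ge, b_ge = b_ge,
                 A_le = A_le, b_le = b_le,
                 feed_names = feeds$name, nutrients = nutr, comp = comp),
            class = "ration_problem")
}

#' Solve a least-cost ration linear program
#'
#' Solves the LP of [build_ration_problem()] by a dense two-phase simplex
#' with Bland's anti-cycling rule (feed amounts implicitly nonnegative).
#' The optimal cost is unique even when the optimal diet is degenerate.
#'
#' @param problem a `ration_problem`.
#' @return an object of class `ration_solution`: `status` ("optimal",
#'   "infeasible" or "unbounded"), `amounts` (named kg DM/d),
#'   `total_cost`, and `achieved` (named nutrient amounts/d).
#' @export
solve_ration <- function(problem) {
  stopifnot(inherits(problem, "ration_problem"))
  res <- solve_lp(problem$cost, A_le = problem$A_le, b_le = problem$b_le,
                  A_ge = problem$A_ge, b_ge = problem$b_ge)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, amounts = NULL,
                          total_cost = NA_real_, achieved = NULL),
                     class = "ration_solution"))
  }
  x <- res$x
  names(x) <- problem$feed_names
  achieved <- as.numeric(problem$comp %*% x)
  names(achieved) <- problem$nutrients
  structure(list(status = "optimal", amounts = x,
                 total_cost = sum(problem$cost * x), achieved = achieved),
            class = "ration_solution")
}

#' @export
print.ration_solution <- function(x, ...) {
  cat("<ration_solution>", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  total cost: %.4f /d\n", x$total_cost))
    for (f in names(x$amounts))
      cat(sprintf("  %-20s %8.3f kg DM/d\n", f, x$amounts[[f]]))
  }
  invisible(x)
}

#' Assemble nutrient requirements from production level
#'
#' Purely table-driven linear assembly of daily requirements:
#' `req_n = maintenance_coefficient_n * body_weight +
#' per_kg_milk_n * milk_yield`. No normative coefficients ship with the
#' package — feeding-system coefficient tables (NRC/CNCPS-style) are the
#' user's input.
#'
#' @param milk_yield kg/d.
#' @param body_weight kg.
#' @param requirement_table data.frame with columns `nutrient`,
#'   `maintenance_coefficient` (per kg BW), `per_kg_milk`, and optional
#'   `max_optional` (absolute cap/d).
#' @param dmi_min,dmi_max optional dry-matter-intake window, kg/d.
#' @return a requirements list suitable for [build_ration_problem()].
#' @export
requirements_from_production <- function(milk_yield, body_weight,
                                         requirement_table,
                                         dmi_min = NULL, dmi_max = NULL) {
  if (missing(requirement_table) || !is.data.frame(requirement_table))
    stop("a requirement table must be supplied")
  need <- c("nutrient", "maintenance_coefficient", "per_kg_milk")
  miss <- setdiff(need, names(requirement_table))
  if (length(miss))
    stop("requirement table missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(milk_yield >= 0, body_weight >= 0)
  nut <- data.frame(
    nutrient = requirement_table$nutrient,
    min = requirement_table$maintenance_coefficient * body_weight +
      requirement_table$per_kg_milk * milk_yield)
  if ("max_optional" %in% names(requirement_table))
    nut$max <- ifelse(is.na(requirement_table$max_optional), Inf,
                      requirement_table$max_optional)
  list(nutrients = nut, dmi_min = dmi_min, dmi_max = dmi_max)
}
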