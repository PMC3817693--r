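#' Whole-structure Cartesian minimization of the low-resolution objective
#'
#' Quasi-Newton (limited-memory BFGS with line search, via
#' `stats::optim(method = "L-BFGS-B")`) descent on the Cartesian
#' coordinates of the movable residues, using the analytic gradients of
#' [total_energy()]. Torsions are re-synchronized from the final
#' coordinates.
#'
#' @param model a [backbone_model()]
#' @param field spline score field, or NULL when the density weight is 0
#' @param weights objective weights (see [default_weights()])
#' @param params energy parameters
#' @param movable logical per-residue mask (default: the model's own mask;
#'   use `rep(TRUE, n)` for all residues)
#' @param max_evals objective evaluation budget (default 2000)
#' @param gtol projected-gradient tolerance (default 1e-4)
#' @param on_frozen what to do when no residue is movable: `"error"`
#'   (default) or `"noop"`
#' @return list with `model`, `final_energy`, `initial_energy`, `n_evals`
#' @export
cartesian_minimize <- function(model, field = NULL, weights = default_weights(),
                               params = default_energy_params(),
                               movable = NULL, max_evals = 2000, gtol = 1e-4,
                               on_frozen = c("error", "noop")) {
  on_frozen <- match.arg(on_frozen)
  n <- n_res(model)
  if (is.null(movable)) movable <- model$movable
  movable <- movable & has_coords(model)
  if (!any(movable)) {
    if (on_frozen == "noop") {
      e0 <- total_energy(model, field, weights, params)$energy
      return(list(model = model, final_energy = e0, initial_energy = e0,
                  n_evals = 1L))
    }
    stop("no movable residues (pass on_frozen = \"noop\" to allow)")
  }
  midx <- which(movable)
  work <- model
  e0 <- total_energy(model, field, weights, params)
  if (!is.finite(e0$energy)) {
    bad <- names(e0$terms)[!is.finite(e0$terms)]
    badat <- which(!apply(is.finite(model$coords), 1, all))
    stop("non-finite starting energy in term(s) ", paste(bad, collapse = ","),
         if (length(badat)) paste0(" (residues ", paste(badat, collapse = ","), ")"))
  }

  x0 <- as.numeric(model$coords[midx, , ])
  cache <- new.env()
  cache$x <- NULL
  evalx <- function(x) {
    if (!is.null(cache$x) && identical(x, cache$x)) return()
    co <- work$coords
    co[midx, , ] <- array(x, c(length(midx), 5, 3))
    work$coords <- co
    r <- total_energy(work, field, weights, params)
    cache$x <- x
    cache$e <- r$energy
    cache$g <- as.numeric(r$grad[midx, , ])
    cache$n <- (if (is.null(cache$n)) 0L else cache$n) + 1L
  }
  fn <- function(x) { evalx(x); cache$e }
  gr <- function(x) { evalx(x); cache$g }
  res <- tryCatch(
    stats::optim(x0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = max_evals, pgtol = gtol, factr = 1e4)),
    error = function(e) list(par = x0, value = e0$energy)
  )
  if (res$value <= e0$energy) {
    co <- model$coords
    co[midx, , ] <- array(res$par, c(length(midx), 5, 3))
    model$coords <- co
    final <- res$value
  } else {
    final <- e0$energy
  }
  model <- detect_breaks(sync_torsions(model))
  list(model = model, final_energy = final, initial_energy = e0$energy,
       n_evals = if (is.null(cache$n)) 1L else cache$n)
}

#' Heal a fragment insertion by whole-structure minimization
#'
#' After a fragment has been superposed and spliced into
#' `inserted_window`, the chain may be geometrically broken at the window
#' edges. All residues are made movable and the objective (with an active
#' bond-geometry weight) pulls the junctions closed. If the largest
#' backbone bond-length deviation still exceeds `bond_tol` after the
#' budget, the model is returned with a `strained` attribute set.
#'
#' @param model a [backbone_model()]
#' @param inserted_window integer pair (start, end) of the spliced window
#'   (recorded in the result; healing moves the entire structure)
#' @param field optional spline score field for the density term
#' @param weights objective weights; `cart_bonded` is raised to at least 1
#' @param params energy parameters
#' @param max_evals evaluation budget (default 400)
#' @param bond_tol maximum tolerated bond-length deviation (default 0.05 A)
#' @return the healed model, with attributes `strained` (logical) and
#'   `max_bond_dev`
#' @export
heal_insertion <- function(model, inserted_window, field = NULL,
                           weights = default_weights(),
                           params = default_energy_params(),
                           max_evals = 400, bond_tol = 0.05) {
  w <- default_weights()
  w[names(weights)] <- weights
  if (w["cart_bonded"] < 1) w["cart_bonded"] <- 1
  if (is.null(field)) w["density"] <- 0
  n <- n_res(model)
  # junction breaks are to be pulled closed, not skipped by the restraints
  hc <- has_coords(model)
  span <- max(1, inserted_window[1] - 1):min(n, inserted_window[2])
  for (i in span)
    if (i < n && hc[i] && hc[i + 1]) model$break_after[i] <- FALSE
  r <- cartesian_minimize(model, field, w, params,
                          movable = rep(TRUE, n), max_evals = max_evals)
  healed <- r$model
  dev <- cart_bonded_energy(healed, params)$max_bond_dev
  attr(healed, "strained") <- dev > bond_tol
  attr(healed, "max_bond_dev") <- dev
  attr(healed, "final_energy") <- r$final_energy
  healed
}
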