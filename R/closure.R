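#' Close a chain break by cyclic coordinate descent
#'
#' Iterates over the movable phi/psi torsions of `segment[1]..cutpoint`
#' (plus the continuation phi at the cutpoint junction); each step applies
#' the closed-form rotation angle that minimizes the summed squared
#' deviation of the three anchor atoms -- mobile copies of N, CA, C of the
#' residue after the cutpoint, built by ideal chain continuation -- from
#' their fixed target coordinates. Omega torsions are held at 180 degrees.
#' Bond lengths and angles are untouched (pure torsion moves); the carbonyl
#' O and CB atoms of the moved residues are re-idealized after closure.
#'
#' @param model a [backbone_model()]
#' @param segment integer pair (start, end) of the movable segment
#'   (positions in the model)
#' @param cutpoint residue position inside the segment at whose C-terminal
#'   junction closure is enforced
#' @param max_iters maximum CCD sweeps (default 100)
#' @param tol target RMS anchor deviation in Angstrom (default 0.08)
#' @param max_step per-step torsion change cap in degrees (default 60)
#' @param alternate alternate the sweep direction between iterations
#' @return list with `model`, `closed`, `final_dev` (Angstrom RMS),
#'   `n_iters` and the per-sweep deviation trace `dev_trace`
#' @export
ccd_close <- function(model, segment, cutpoint, max_iters = 100, tol = 0.08,
                      max_step = 60, alternate = FALSE) {
  s <- segment[1]; e <- segment[2]
  n <- n_res(model)
  if (cutpoint < s || cutpoint > e) stop("cutpoint must lie inside the segment")
  if (cutpoint + 1 > n) stop("no anchor residue after the cutpoint")
  if (!all(has_coords(model)[c(s:cutpoint, cutpoint + 1)]))
    stop("segment or anchor residues lack coordinates")
  geom <- ideal_geometry()
  nm <- cutpoint - s + 1
  if (nm < 1) stop("segment with zero movable torsions")

  # mobile atom matrix: N,CA,C of s..cutpoint then virtual N,CA,C of cutpoint+1
  M <- matrix(NA_real_, 3 * nm + 3, 3)
  for (r in s:cutpoint)
    for (a in 1:3) M[3 * (r - s) + a, ] <- model$coords[r, a, ]
  iv <- 3 * nm  # offset of virtuals
  tor <- model$torsions
  psi_c <- tor[cutpoint, "psi"]; if (!is.finite(psi_c)) psi_c <- 180
  phi_v <- tor[cutpoint + 1, "phi"]; if (!is.finite(phi_v)) phi_v <- -120
  rebuild_virtuals <- function(M, psi_c, phi_v) {
    N <- M[iv - 2, ]; CA <- M[iv - 1, ]; C <- M[iv, ]
    Nv <- place_atom(N, CA, C, geom$b_c_n, geom$a_ca_c_n, psi_c)
    CAv <- place_atom(CA, C, Nv, geom$b_n_ca, geom$a_c_n_ca, 180)
    Cv <- place_atom(C, Nv, CAv, geom$b_ca_c, geom$a_n_ca_c, phi_v)
    M[iv + 1, ] <- Nv; M[iv + 2, ] <- CAv; M[iv + 3, ] <- Cv
    M
  }
  M <- rebuild_virtuals(M, psi_c, phi_v)
  FT <- rbind(model$coords[cutpoint + 1, 1, ],
              model$coords[cutpoint + 1, 2, ],
              model$coords[cutpoint + 1, 3, ])
  devf <- function(M) sqrt(mean(rowSums((M[iv + 1:3, , drop = FALSE] - FT)^2)))

  # DOF table: residue phi/psi plus the junction continuation phi
  dofs <- list()
  for (r in s:cutpoint) {
    dofs[[length(dofs) + 1]] <- list(p1 = 3 * (r - s) + 1, p2 = 3 * (r - s) + 2,
                                     first_moving = 3 * (r - s) + 3)  # phi(r)
    dofs[[length(dofs) + 1]] <- list(p1 = 3 * (r - s) + 2, p2 = 3 * (r - s) + 3,
                                     first_moving = 3 * (r - s) + 4)  # psi(r)
  }
  dofs[[length(dofs) + 1]] <- list(p1 = iv + 1, p2 = iv + 2,
                                   first_moving = iv + 3)             # phi at junction

  dev0 <- devf(M)
  trace <- dev0
  if (dev0 <= tol) {
    return(list(model = model, closed = TRUE, final_dev = dev0, n_iters = 0L,
                dev_trace = trace))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    ord <- seq_along(dofs)
    if (alternate && it %% 2 == 0) ord <- rev(ord)
    for (k in ord) {
      d <- dofs[[k]]
      P <- M[d$p1, ]; Q <- M[d$p2, ]
      u <- vunit(Q - P)
      rows <- d$first_moving:nrow(M)
      # closed-form optimal rotation of the anchor copies about the axis
      a_c <- 0; b_c <- 0
      for (j in 1:3) {
        mrow <- iv + j
        if (mrow < d$first_moving) next
        Mp <- M[mrow, ]
        Op <- P + sum((Mp - P) * u) * u
        rv <- Mp - Op
        rl <- vnorm(rv)
        if (rl < 1e-9) next
        sh <- rv / rl
        th <- vcross(u, sh)
        Fv <- FT[j, ] - Op
        a_c <- a_c + rl * sum(Fv * sh)
        b_c <- b_c + rl * sum(Fv * th)
      }
      if (a_c == 0 && b_c == 0) next
      ang <- atan2(b_c, a_c) * 180 / pi
      ang <- max(-max_step, min(max_step, ang))
      if (abs(ang) < 1e-10) next
      M[rows, ] <- rotate_about_axis(M[rows, , drop = FALSE], P, u, ang)
    }
    dv <- devf(M)
    trace <- c(trace, dv)
    if (dv <= tol || it >= max_iters) break
  }
  final <- devf(M)
  closed <- final <= tol

  co <- model$coords
  for (r in s:cutpoint)
    for (a in 1:3) co[r, a, ] <- M[3 * (r - s) + a, ]
  model$coords <- co
  # re-idealize O and CB of the moved residues
  for (r in s:cutpoint) {
    N <- co[r, 1, ]; CA <- co[r, 2, ]; C <- co[r, 3, ]
    nn <- if (r < cutpoint) M[3 * (r - s) + 4, ] else model$coords[cutpoint + 1, 1, ]
    ocb <- place_o_cb(N, CA, C, n_next = nn, geom = geom)
    model$coords[r, 4, ] <- ocb$O
    model$coords[r, 5, ] <- ocb$CB
  }
  dcn <- vnorm(model$coords[cutpoint + 1, 1, ] - model$coords[cutpoint, 3, ])
  model$break_after[cutpoint] <- !(dcn > 0.5 && dcn < 3.0)
  model <- sync_torsions(model)
  list(model = model, closed = closed, final_dev = final, n_iters = it,
       dev_trace = trace)
}
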