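# grid-based counterparts of the closed-form delay selection results

# quadratic interpolation of a peak through three points around index i
quad_refine <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(x[i])
  dx <- x[2] - x[1]
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(x[i])
  x[i] + 0.5 * dx * (y[i - 1] - y[i + 1]) / denom
}

#' Grid argmax of the axonal learning term
#'
#' Evaluates [learning_term_axonal] on a delay grid (0.1 ms spacing by
#' default, the precision at which selected delays are reported) and
#' returns the shortest maximising delay, refined by quadratic
#' interpolation through the peak bin. Serves as the independent
#' cross-check of the closed form in [selected_delay].
#'
#' @param f_mod modulation frequency in Hz.
#' @param window an [stdp_window].
#' @param delay_range `[d_min, d_max]` searched, in ms.
#' @param step grid spacing in ms.
#' @param refine logical; quadratic peak refinement.
#' @return the shortest maximising delay in ms.
#' @export
selected_delay_grid <- function(f_mod, window = stdp_window(),
                                delay_range = c(1, 10), step = 0.1,
                                refine = TRUE) {
  grid <- seq(delay_range[1], delay_range[2], by = step)
  drv <- drive_spec(f_mod = f_mod)
  lt <- learning_term_axonal(grid, drv, window = window)
  is_peak <- c(FALSE, diff(sign(diff(lt))) < 0, FALSE) |
    seq_along(lt) == which.max(lt)
  cand <- which(is_peak)
  pos <- vapply(cand, function(i) quad_refine(grid, lt, i), numeric(1))
  height <- learning_term_axonal(pos, drv, window = window)
  best <- max(height)
  # shortest refined maximum numerically tied with the global one
  short <- min(pos[height > best - 1e-6 * abs(best)])
  if (refine) short
  else grid[which.min(abs(grid - short))]
}

#' Slope of the potentiation ridges of the 2D learning term
#'
#' Evaluates [learning_term_2d] on an (axonal x dendritic) grid, tracks
#' one potentiation ridge across dendritic-delay columns (per column, the
#' quadratically refined local maximum nearest the ridge's previous
#' position) and fits a least-squares line of axonal delay versus
#' dendritic delay along it. The learning term depends on the delays only
#' through their difference, so the expected slope is 1.0.
#'
#' @param drive a [drive_spec].
#' @param ff a [feedforward_spec].
#' @param epsp an [epsp_params].
#' @param window an [stdp_window].
#' @param axonal_range,dendritic_range grid ranges in ms.
#' @param step grid spacing in ms.
#' @return list with `slope`, `intercept`, and the tracked `ridge` points.
#' @export
ridge_slope_2d <- function(drive, ff = feedforward_spec(),
                           epsp = epsp_params("medium"),
                           window = stdp_window(),
                           axonal_range = c(0, 10),
                           dendritic_range = c(0, 10), step = 0.1) {
  a_grid <- seq(axonal_range[1], axonal_range[2], by = step)
  d_grid <- seq(dendritic_range[1], dendritic_range[2], by = step)
  # ridge anchor: shortest resonant axonal delay at zero dendritic delay
  anchor <- selected_delay(drive$f_mod, window)
  period <- 1000 / drive$f_mod
  while (anchor > axonal_range[2]) anchor <- anchor - period
  if (anchor < axonal_range[1]) anchor <- anchor + period
  prev <- anchor
  ridge_a <- ridge_d <- numeric(0)
  for (dd in d_grid) {
    lt <- learning_term_2d(a_grid, dd, drive, ff, epsp, window)
    peaks <- which(c(FALSE, diff(sign(diff(lt))) < 0, FALSE) & lt > 0)
    if (length(peaks) == 0) break
    i <- peaks[which.min(abs(a_grid[peaks] - prev))]
    if (abs(a_grid[i] - prev) > period / 4) break  # ridge left the grid
    a_ref <- quad_refine(a_grid, lt, i)
    ridge_a <- c(ridge_a, a_ref)
    ridge_d <- c(ridge_d, dd)
    prev <- a_ref
  }
  if (length(ridge_a) < 3) stop("ridge too short to fit")
  fit <- stats::lm.fit(cbind(1, ridge_d), ridge_a)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       ridge = data.frame(dendritic = ridge_d, axonal = ridge_a))
}
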