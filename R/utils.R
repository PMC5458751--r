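# Internal helpers shared across modules.

# Classed conditions so callers can distinguish bad configuration from
# geometric impossibility (requested content does not fit the volume).
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("chc_config_error", "chc_error")))
}

stop_capacity <- function(...) {
  stop(errorCondition(paste0(...), class = c("chc_capacity_error", "chc_error")))
}

stop_chc <- function(...) {
  stop(errorCondition(paste0(...), class = "chc_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unit vector; zero-length input is a programming error upstream.
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop_chc("cannot normalise zero vector")
  v / n
}

# Rotate 3-vector v about unit axis u by angle theta (Rodrigues).
rotate3 <- function(v, u, theta) {
  ct <- cos(theta); st <- sin(theta)
  v * ct + crossp(u, v) * st + u * sum(u * v) * (1 - ct)
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# An arbitrary unit vector perpendicular to d.
perp_of <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  unit(crossp(d, ref))
}

# Distance from points (n x 3) to a segment p0-p1.
dist_point_segment <- function(pts, p0, p1) {
  pts <- matrix(pts, ncol = 3)
  d <- p1 - p0
  l2 <- sum(d^2)
  if (l2 < .Machine$double.eps) {
    return(sqrt(rowSums(sweep(pts, 2, p0)^2)))
  }
  t <- (sweep(pts, 2, p0) %*% d) / l2
  t <- pmin(1, pmax(0, as.numeric(t)))
  proj <- cbind(p0[1] + t * d[1], p0[2] + t * d[2], p0[3] + t * d[3])
  sqrt(rowSums((pts - proj)^2))
}

# Resample a polyline (n x 3) at regular arc spacing (keeps both endpoints).
resample_polyline <- function(pts, spacing) {
  pts <- matrix(pts, ncol = 3)
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total < spacing) return(pts[c(1, nrow(pts)), , drop = FALSE])
  s <- seq(0, total, by = spacing)
  if (s[length(s)] < total) s <- c(s, total)
  out <- sapply(seq_len(3), function(k) stats::approx(arc, pts[, k], xout = s)$y)
  matrix(out, ncol = 3)
}
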