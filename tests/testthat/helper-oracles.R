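# Independent naive oracles, written as explicit element-by-element loops
# so they share no code path with the package implementations.

oracle_bias <- function(dev) {
  if (length(dev) == 0) return(NA_real_)
  s <- 0
  for (d in dev) s <- s + d
  s / length(dev)
}

oracle_mard <- function(dev) {
  if (length(dev) == 0) return(NA_real_)
  s <- 0
  for (d in dev) s <- s + abs(d)
  s / length(dev)
}

oracle_sd <- function(dev) {
  n <- length(dev)
  if (n < 2) return(NA_real_)
  m <- oracle_bias(dev)
  ss <- 0
  for (d in dev) ss <- ss + (d - m)^2
  sqrt(ss / (n - 1))
}

# Error-grid oracle: mgcv::in.out (a different point-in-polygon algorithm
# from a different author) applied to the cumulative zone polygons in
# safest-first order. Boundary behavior is unspecified in mgcv, so this
# oracle is only used on continuous random points (boundaries have measure
# zero).
oracle_zone <- function(ref, met, zones = parkes_zones()) {
  labels <- names(zones$zones)
  out <- character(length(ref))
  for (i in seq_along(ref)) {
    out[i] <- "E"
    for (k in seq_along(labels)) {
      bnd <- zones$zones[[k]]
      bnd <- rbind(bnd, bnd[1, ])
      if (mgcv::in.out(bnd, matrix(c(ref[i], met[i]), ncol = 2))) {
        out[i] <- labels[k]
        break
      }
    }
  }
  out
}
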