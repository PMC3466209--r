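# Shared fixtures: small stacks, synthetic transport summaries, and tiny
# utilities the tests need (connected-component labelling, bilinear image
# rotation). All fixtures are built in code; nothing is read from disk.

methods_stack <- function() metal_coated_sin_stack(sin_thickness = 60)

thin_stack <- function(thickness = 1e-3) {
  film_stack(layer(material_library()$SiN, thickness))
}

# a transport_summary-shaped object built from given exit coordinates,
# binned independently of run_transport's internals
fake_summary <- function(x, y, bin_width = 2, n_total = length(x)) {
  bin1 <- function(v, edges) {
    idx <- findInterval(v, edges, rightmost.closed = TRUE)
    data.frame(bin_center = (edges[-length(edges)] + edges[-1]) / 2,
               count = tabulate(idx, nbins = length(edges) - 1))
  }
  if (length(x) == 0) {
    empty <- data.frame(bin_center = numeric(0), count = integer(0))
    return(structure(list(
      n_electrons = n_total, n_transmitted = 0L, n_backscattered = 0L,
      n_absorbed = n_total,
      fractions = c(transmitted = 0, backscattered = 0, absorbed = 1),
      exit_x = x, exit_y = y, exit_lateral_profile = empty,
      exit_radial_histogram = empty, bin_width = bin_width,
      voltage = 4, seed = 0L
    ), class = "transport_summary"))
  }
  m <- max(abs(x)) + bin_width
  k <- ceiling(m / bin_width)
  lat <- bin1(x, seq(-k * bin_width, k * bin_width, by = bin_width))
  r <- sqrt(x^2 + y^2)
  rad <- bin1(r, seq(0, max(r) + bin_width, by = bin_width))
  structure(list(
    n_electrons = n_total, n_transmitted = length(x),
    n_backscattered = 0L, n_absorbed = n_total - length(x),
    fractions = c(transmitted = length(x) / n_total, backscattered = 0,
                  absorbed = 1 - length(x) / n_total),
    exit_x = x, exit_y = y,
    exit_lateral_profile = lat, exit_radial_histogram = rad,
    bin_width = bin_width, voltage = 4, seed = 0L
  ), class = "transport_summary")
}

# 4-connected component count of a logical matrix (simple BFS labelling)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] &&
              lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- nxt
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  nxt
}

# rotate a matrix about its centre by `angle` rad with bilinear sampling;
# out-of-range samples get NA
rotate_bilinear <- function(V, angle) {
  nr <- nrow(V); nc <- ncol(V)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  out <- matrix(NA_real_, nr, nc)
  ca <- cos(angle); sa <- sin(angle)
  for (j in seq_len(nc)) {
    dx <- j - cx
    for (i in seq_len(nr)) {
      dy <- i - cy
      xs <- cx + ca * dx - sa * dy
      ys <- cy + sa * dx + ca * dy
      x0 <- floor(xs); y0 <- floor(ys)
      if (x0 >= 1 && x0 < nc && y0 >= 1 && y0 < nr) {
        fx <- xs - x0; fy <- ys - y0
        out[i, j] <- V[y0, x0] * (1 - fx) * (1 - fy) +
          V[y0, x0 + 1] * fx * (1 - fy) +
          V[y0 + 1, x0] * (1 - fx) * fy +
          V[y0 + 1, x0 + 1] * fx * fy
      }
    }
  }
  out
}

# screened-Rutherford angular density (unnormalized) in mu = cos(theta)
sr_angular_density <- function(mu, alpha) 1 / (1 - mu + 2 * alpha)^2
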