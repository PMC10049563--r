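# Shared fixtures. Large generator draws are cached so several test
# files can reuse the same n = 10,000 calibration check cheaply.
.fixture_cache <- new.env()

big_draw <- function(area, n = 10000, seed = 777) {
  key <- paste(area, n, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      generate_area(area_generator_config(area, n = n), seed = seed)
  }
  .fixture_cache[[key]]
}

# minimal hand-built samples table with controllable concentrations
make_samples <- function(conc_list, area = "A") {
  n <- length(conc_list[[1]])
  out <- data.frame(sample_id = sprintf("S%02d", seq_len(n)), area = area,
                    x = seq_len(n), y = rev(seq_len(n)),
                    stringsAsFactors = FALSE)
  for (el in hm_elements()) {
    out[[el]] <- if (el %in% names(conc_list)) conc_list[[el]] else rep(1, n)
  }
  out
}

# background-level concentration vector (every ratio exactly 1)
background_vector <- function(refs = element_references()) {
  stats::setNames(refs$background, refs$element)
}

area_mean_vector <- function(area) {
  m <- area_marginals(area)
  stats::setNames(m$mean, m$element)
}

# independent oracle: naive double loop over cells and points
naive_idw <- function(x, y, v, grid, power = 2, eps = 1e-9 * grid$cell_size) {
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      cx <- grid$x_min + (c - 0.5) * grid$cell_size
      cy <- grid$y_min + (grid$n_rows - r + 0.5) * grid$cell_size
      d <- sqrt((x - cx)^2 + (y - cy)^2)
      if (any(d < eps)) {
        out[r, c] <- v[which(d < eps)[1]]
      } else {
        w <- d^(-power)
        out[r, c] <- sum(w * v) / sum(w)
      }
    }
  }
  out
}
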