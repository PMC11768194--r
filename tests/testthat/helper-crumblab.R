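# shared helpers: independent oracles used against the implementation

# brute-force pixel count of a rasterized disk (double loop, no vectorized
# shortcuts shared with the generator)
disk_pixel_count <- function(cx, cy, r) {
  n <- 0L
  for (row in floor(cy - r - 1):ceiling(cy + r + 1)) {
    for (col in floor(cx - r - 1):ceiling(cx + r + 1)) {
      if ((col - cx)^2 + (row - cy)^2 <= r^2) n <- n + 1L
    }
  }
  n
}

# reference flood-fill connected-component labelling (stack based)
flood_fill_labels <- function(fg, connectivity = 8) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!fg[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[k, 1]; c2 <- p[2] + nb[k, 2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            fg[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# do two letter strings share at least one letter?
share_letter <- function(a, b) {
  length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
}

# random grouped data with k groups x n replicates
random_group_data <- function(k, n = 3, mean_spread = 2, sd = 0.5) {
  mu <- runif(k, 0, mean_spread)
  group_data(rep(paste0("g", seq_len(k)), each = n),
             rnorm(k * n, mean = rep(mu, each = n), sd = sd))
}

round_trip_fields <- c("t_hydr", "t1", "c1", "amplitude", "stability",
                       "c2", "c3", "t3", "gelling_mid", "c4", "c5")
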