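# shared fixture builders

traj_from_points <- function(..., dt_min = 15, gradient_axis = c(1, 0)) {
  trajectory(rbind(...), dt_min = dt_min, gradient_axis = gradient_axis)
}

# independent simple-random-walk oracle (plain R, no package sampler):
# M exponential steps with uniform directions; returns positions matrix
oracle_random_walk <- function(M) {
  len <- stats::rexp(M)
  th <- stats::runif(M, -pi, pi)
  rbind(c(0, 0), cbind(cumsum(len * cos(th)), cumsum(len * sin(th))))
}

rotate2 <- function(xy, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy %*% t(R)
}

# independent flood-fill connectivity check (4-adjacency) on a CPM grid
grid_is_connected <- function(grid) {
  w <- which(grid == 1L, arr.ind = TRUE)
  if (!nrow(w)) return(FALSE)
  n <- nrow(grid)
  m <- ncol(grid)
  seen <- matrix(FALSE, n, m)
  queue <- list(w[1, ])
  seen[w[1, 1], w[1, 2]] <- TRUE
  count <- 1L
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      x <- cur[1] + d[1]; y <- cur[2] + d[2]
      if (x < 1 || x > n || y < 1 || y > m) next
      if (grid[x, y] == 1L && !seen[x, y]) {
        seen[x, y] <- TRUE
        count <- count + 1L
        queue[[length(queue) + 1L]] <- c(x, y)
      }
    }
  }
  count == sum(grid)
}

# hole check: medium (incl. a padded border) must be one 8-connected piece
# (the complement of a 4-connected cell carries 8-connectivity)
grid_has_no_holes <- function(grid) {
  inv <- 1L - grid
  padded <- matrix(1L, nrow(grid) + 2, ncol(grid) + 2)
  padded[2:(nrow(grid) + 1), 2:(ncol(grid) + 1)] <- inv
  n <- nrow(padded); m <- ncol(padded)
  seen <- matrix(FALSE, n, m)
  queue <- list(c(1L, 1L))
  seen[1, 1] <- TRUE
  count <- 1L
  dirs <- expand.grid(dx = -1:1, dy = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0), ]
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (k in seq_len(nrow(dirs))) {
      x <- cur[1] + dirs$dx[k]; y <- cur[2] + dirs$dy[k]
      if (x < 1 || x > n || y < 1 || y > m) next
      if (padded[x, y] == 1L && !seen[x, y]) {
        seen[x, y] <- TRUE
        count <- count + 1L
        queue[[length(queue) + 1L]] <- c(x, y)
      }
    }
  }
  count == sum(padded)
}
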