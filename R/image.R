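# Grayscale image utilities.
#
# Images are numeric matrices in [0, 1]; element [v + 1, u + 1] is the pixel
# at 0-based coordinates (u, v), u to the right and v down.

#' Read a grayscale image
#'
#' Supports 8/16-bit grayscale PNG and plain or binary PGM (P2/P5). Color
#' PNGs are converted to luminance. Values are returned in \[0, 1\].
#'
#' @param path image file path.
#' @return numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
    return(img)
  }
  if (ext %in% c("pgm", "ppm")) return(read_pgm(path))
  stop("unsupported image format '", ext, "' (use png or pgm)")
}

#' Write a grayscale image
#'
#' PNG output is 8-bit (the `png` package does not write 16-bit channels);
#' 16-bit output is available through binary PGM (P5). Both round-trip with
#' [read_image()].
#'
#' @param img numeric matrix in \[0, 1\].
#' @param path output path; extension selects the format.
#' @param bit_depth 8 or 16 (16 for PGM only).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  stopifnot(is.matrix(img), bit_depth %in% c(8L, 16L))
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8L) {
      stop("PNG output is 8-bit; use a .pgm path for 16-bit images")
    }
    png::writePNG(img, path)
  } else if (ext == "pgm") {
    write_pgm(img, path, bit_depth = bit_depth)
  } else {
    stop("unsupported image format '", ext, "' (use png or pgm)")
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pnm_token(con)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  w <- as.integer(read_pnm_token(con))
  h <- as.integer(read_pnm_token(con))
  maxval <- as.integer(read_pnm_token(con))
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval < 256) {
    vals <- as.integer(readBin(con, "raw", n = n))
  } else {
    b <- readBin(con, "raw", n = 2L * n)
    vals <- as.integer(b[seq(1, 2 * n, 2)]) * 256L + as.integer(b[seq(2, 2 * n, 2)])
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

read_pnm_token <- function(con) {
  tok <- ""
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch) || !nzchar(ch)) break
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(tok)) break else next
    }
    tok <- paste0(tok, ch)
  }
  tok
}

write_pgm <- function(img, path, bit_depth = 16L) {
  maxval <- if (bit_depth == 8L) 255L else 65535L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img), nrow(img), maxval),
            con, eos = NULL)
  q <- as.vector(t(round(img * maxval)))  # row-major pixel order
  if (bit_depth == 8L) {
    writeBin(as.raw(q), con)
  } else {
    b <- raw(2L * length(q))
    b[seq(1, length(b), 2)] <- as.raw(q %/% 256)
    b[seq(2, length(b), 2)] <- as.raw(q %% 256)
    writeBin(b, con)
  }
  invisible(path)
}

# Separable Gaussian smoothing with replicate edge handling.
gaussian_smooth <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  m <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-m, m))^2 / (2 * sigma^2))
  k <- k / sum(k)
  img <- conv_rows(img, k, m)
  t(conv_rows(t(img), k, m))
}

conv_rows <- function(img, k, m) {
  h <- nrow(img); w <- ncol(img)
  pad <- cbind(img[, rep(1L, m), drop = FALSE], img,
               img[, rep(w, m), drop = FALSE])
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    out <- out + k[i] * pad[, i:(i + w - 1L), drop = FALSE]
  }
  out
}

# Otsu's threshold on values in [0, 1].
otsu_threshold <- function(vals, nbins = 256L) {
  vals <- vals[is.finite(vals)]
  h <- tabulate(pmin(pmax(floor(vals * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (seq_len(nbins) - 0.5) / nbins
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -1
  mids[which.max(sigma_b)]
}

# Connected-component labeling (4-connectivity) by row runs + union-find.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  runs_row <- integer(0); runs_s <- integer(0); runs_e <- integer(0)
  row_first <- integer(h + 1L)
  cnt <- 0L
  for (r in seq_len(h)) {
    row_first[r] <- cnt + 1L
    x <- mask[r, ]
    if (any(x)) {
      rl <- rle(x)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      on <- which(rl$values)
      for (i in on) {
        cnt <- cnt + 1L
        runs_row[cnt] <- r; runs_s[cnt] <- starts[i]; runs_e[cnt] <- ends[i]
      }
    }
  }
  row_first[h + 1L] <- cnt + 1L
  parent <- seq_len(cnt)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in 2:max(2L, h)) {
    if (r > h) break
    a0 <- row_first[r - 1L]; a1 <- row_first[r] - 1L
    b0 <- row_first[r]; b1 <- row_first[r + 1L] - 1L
    if (a1 < a0 || b1 < b0) next
    for (i in a0:a1) for (j in b0:b1) {
      if (runs_s[i] <= runs_e[j] && runs_s[j] <= runs_e[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  lab <- matrix(0L, h, w)
  if (cnt > 0) {
    roots <- vapply(seq_len(cnt), find, integer(1))
    ids <- match(roots, unique(roots))
    for (i in seq_len(cnt)) {
      lab[runs_row[i], runs_s[i]:runs_e[i]] <- ids[i]
    }
  }
  lab
}

# Area of the convex hull of integer pixel coordinates.
hull_area <- function(uv) {
  if (nrow(uv) < 3) return(0)
  h <- grDevices::chull(uv)
  p <- uv[h, , drop = FALSE]
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

# Point-in-polygon (ray casting); poly is n x 2, closed implicitly.
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2])) {
      xint <- poly[j, 1] + (pt[2] - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1]) / (poly[i, 2] - poly[j, 2])
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Subpixel iso-contour loops around a set of pixels, from marching squares
# (grDevices::contourLines) on the image. Returns closed loops in (u, v).
iso_contours <- function(img, level) {
  h <- nrow(img); w <- ncol(img)
  cl <- grDevices::contourLines(x = 0:(h - 1), y = 0:(w - 1), z = img,
                                levels = level)
  lapply(cl, function(li) {
    uv <- cbind(li$y, li$x)  # contourLines x runs over rows (= v)
    closed <- sqrt(sum((uv[1, ] - uv[nrow(uv), ])^2)) < 1e-9
    if (closed) uv <- uv[-nrow(uv), , drop = FALSE]
    list(points = uv, closed = closed)
  })
}
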