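# Independent brute-force oracles and small fixture builders.
# The oracles are deliberately written as plain loops, sharing no code with
# the package's vectorized/C++ implementations.

# even-odd ray casting: is point (px, py) inside the polygon?
point_in_polygon_oracle <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    if ((yi <= py) != (yj <= py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# O(H*W*V) rasterization: loop over every pixel center and every polygon
# (in order, last containing polygon wins)
rasterize_oracle <- function(H, W, polys, values, background = 255L) {
  lab <- matrix(background, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      px <- j - 1 + 0.5
      py <- i - 1 + 0.5
      for (p in seq_along(polys)) {
        if (point_in_polygon_oracle(px, py, polys[[p]])) lab[i, j] <- values[p]
      }
    }
  }
  lab
}

confusion_oracle <- function(true_labels, pred_labels, K, unl = 255L) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(true_labels)) {
    t <- true_labels[i]
    if (t == unl) next
    p <- pred_labels[i]
    cm[t + 1, p + 1] <- cm[t + 1, p + 1] + 1L
  }
  cm
}

argmax_oracle <- function(values) {
  d <- dim(values)
  out <- matrix(0L, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      best <- values[i, j, 1]
      bid <- 0L
      for (k in seq_len(d[3])[-1]) {
        if (values[i, j, k] > best) {
          best <- values[i, j, k]
          bid <- k - 1L
        }
      }
      out[i, j] <- bid
    }
  }
  out
}

cross_entropy_oracle <- function(probs, labels, unl = 255L) {
  total <- 0
  n <- 0
  d <- dim(probs)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      lab <- labels[i, j]
      if (lab == unl) next
      total <- total - log(probs[i, j, lab + 1])
      n <- n + 1
    }
  }
  total / n
}

pooled_oracle <- function(cm, ids) {
  tp <- 0; fp <- 0; fn <- 0
  for (c in ids) {
    i <- c + 1
    tp <- tp + cm[i, i]
    fp <- fp + sum(cm[, i]) - cm[i, i]
    fn <- fn + sum(cm[i, ]) - cm[i, i]
  }
  c(precision = tp / (tp + fp), recall = tp / (tp + fn),
    dice = 2 * tp / (2 * tp + fp + fn))
}

# random simple polygon: points on a circle with jittered radii (star-shaped,
# hence simple)
random_polygon <- function(cx, cy, rmax, nv = sample(3:8, 1)) {
  ang <- sort(runif(nv, 0, 2 * pi))
  r <- runif(nv, 0.2 * rmax, rmax)
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# minimal annotation set: triangles, mostly for split/IO plumbing
make_annset <- function(n_cases, anns_per_case, spacing = 0.24, size = 64L) {
  anns <- list()
  ids <- sprintf("case_%03d", seq_len(n_cases))
  for (ci in seq_len(n_cases)) {
    k <- anns_per_case[(ci - 1) %% length(anns_per_case) + 1]
    for (a in seq_len(k)) {
      anns[[length(anns) + 1]] <- polygon_annotation(
        ids[ci], (a - 1) %% 15,
        cbind(c(1, 20, 10) + a, c(1, 1, 20) + a), a)
    }
  }
  cases <- data.frame(case_id = ids, image = NA_character_,
                      spacing = spacing, width = size, height = size,
                      stringsAsFactors = FALSE)
  annotation_set(anns, cases)
}

# a tiny fully-annotated labeled image with vertical class stripes
stripe_image <- function(size = 32L, classes = c(0L, 1L), spacing = 0.5) {
  labels <- matrix(rep(classes, each = ceiling(size / length(classes)),
                       length.out = size),
                   size, size, byrow = TRUE)
  base <- matrix(c(40, 40, 200, 200, 40, 40, 40, 200, 40), 3, 3, byrow = TRUE)
  pal <- base[rep(1:3, length.out = 15), ]  # one row per possible class id
  pixels <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    pixels[, , ch] <- matrix(pal[labels + 1, ch], size, size)
  }
  labeled_image(pixels, labels, spacing, "stripes")
}

# deterministic stub "model" whose predict() is a pure per-pixel function
stub_model <- function(fn) structure(list(fn = fn), class = "stub_model")
predict.stub_model <- function(object, pixels, ...) object$fn(pixels)
registerS3method("predict", "stub_model", predict.stub_model,
                 envir = asNamespace("stats"))
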