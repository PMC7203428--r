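#' Head classifier specification
#'
#' A feed-forward multilayer perceptron with one hidden layer (default 10
#' neurons, logistic activations throughout) mapping a HOG descriptor to a
#' head probability. Samples are split into training / validation / test
#' subsets (default 70/15/15); training is mini-batch backpropagation with
#' momentum and early stopping on the validation cross-entropy.
#'
#' @param hidden hidden-layer size.
#' @param split fractions for training, validation and test; must sum to 1.
#' @param learning_rate,momentum,batch_size,max_epochs backpropagation
#'   hyper-parameters.
#' @param patience early-stopping patience in epochs (validation loss).
#' @param seed RNG seed for the split, weight init and batch order.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(hidden = 10, split = c(0.70, 0.15, 0.15),
                            learning_rate = 0.1, momentum = 0.9,
                            batch_size = 32, max_epochs = 200,
                            patience = 20, seed = 1) {
  stopifnot(abs(sum(split) - 1) < 1e-8, length(split) == 3, hidden >= 1)
  structure(list(hidden = hidden, split = split,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, seed = seed),
            class = "classifier_spec")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.mlp_forward <- function(w, X) {
  H <- .sigmoid(sweep(X %*% w$W1, 2, w$b1, "+"))
  p <- .sigmoid(drop(H %*% w$W2) + w$b2)
  list(H = H, p = p)
}

.xent <- function(p, y) -mean(y * log(pmax(p, 1e-12)) +
                              (1 - y) * log(pmax(1 - p, 1e-12)))

.confusion <- function(p, y, threshold = 0.5) {
  pred <- as.integer(p >= threshold)
  tibble(tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
         fn = sum(pred == 0 & y == 1), tn = sum(pred == 0 & y == 0),
         accuracy = mean(pred == y))
}

#' Train the head / non-head classifier
#'
#' @param features numeric matrix, one row per sample (HOG descriptors).
#' @param labels 0/1 vector (1 = head centred in the patch).
#' @param spec a [classifier_spec()].
#' @return an object of class `head_mlp` with weights, feature scaling and
#'   per-split confusion matrices; use [predict()] for head probabilities.
#' @export
train_head_classifier <- function(features, labels, spec = classifier_spec()) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) {
    abort("both classes (head / non-head) must be present for training",
          class = "hooploc_degenerate_training")
  }
  n <- nrow(X)
  with_seed(spec$seed, {
    idx <- sample.int(n)
    n_tr <- floor(spec$split[1] * n)
    n_va <- floor(spec$split[2] * n)
    sets <- list(train = idx[seq_len(n_tr)],
                 validation = idx[n_tr + seq_len(n_va)],
                 test = idx[(n_tr + n_va + 1):n])
    ctr <- colMeans(X[sets$train, , drop = FALSE])
    scl <- pmax(apply(X[sets$train, , drop = FALSE], 2, stats::sd), 1e-6)
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    d <- ncol(X)
    H <- spec$hidden
    w <- list(W1 = matrix(stats::rnorm(d * H, 0, 1 / sqrt(d)), d, H),
              b1 = numeric(H),
              W2 = stats::rnorm(H, 0, 1 / sqrt(H)),
              b2 = 0)
    v <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, W2 = w$W2 * 0, b2 = 0)
    Xtr <- Xs[sets$train, , drop = FALSE]; ytr <- y[sets$train]
    Xva <- Xs[sets$validation, , drop = FALSE]; yva <- y[sets$validation]
    best <- list(loss = Inf, w = w, epoch = 0)
    stall <- 0
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(nrow(Xtr))
      starts <- seq(1, nrow(Xtr), by = spec$batch_size)
      for (s in starts) {
        b <- ord[s:min(s + spec$batch_size - 1, nrow(Xtr))]
        Xb <- Xtr[b, , drop = FALSE]; yb <- ytr[b]
        fw <- .mlp_forward(w, Xb)
        # backprop: logistic output + cross-entropy -> delta = p - y
        d_out <- (fw$p - yb) / length(b)
        gW2 <- drop(crossprod(fw$H, d_out))
        gb2 <- sum(d_out)
        d_hid <- (d_out %*% t(w$W2)) * fw$H * (1 - fw$H)
        gW1 <- crossprod(Xb, d_hid)
        gb1 <- colSums(d_hid)
        v$W1 <- spec$momentum * v$W1 - spec$learning_rate * gW1
        v$b1 <- spec$momentum * v$b1 - spec$learning_rate * gb1
        v$W2 <- spec$momentum * v$W2 - spec$learning_rate * gW2
        v$b2 <- spec$momentum * v$b2 - spec$learning_rate * gb2
        w$W1 <- w$W1 + v$W1; w$b1 <- w$b1 + v$b1
        w$W2 <- w$W2 + v$W2; w$b2 <- w$b2 + v$b2
      }
      val_loss <- .xent(.mlp_forward(w, Xva)$p, yva)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, w = w, epoch = epoch)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= spec$patience) break
      }
    }
    w <- best$w
    metrics <- purrr::imap_dfr(sets, function(ii, nm) {
      p <- .mlp_forward(w, Xs[ii, , drop = FALSE])$p
      dplyr::bind_cols(tibble(subset = nm, n = length(ii),
                              loss = .xent(p, y[ii])),
                       .confusion(p, y[ii]))
    })
    structure(list(weights = w, center = ctr, scale = scl, spec = spec,
                   metrics = metrics, best_epoch = best$epoch,
                   splits = sets),
              class = "head_mlp")
  })
}

#' @export
print.head_mlp <- function(x, ...) {
  cat("head classifier MLP:", length(x$center), "-",
      ncol(x$weights$W1), "- 1 (best epoch", x$best_epoch, ")\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname train_head_classifier
#' @param object a `head_mlp`.
#' @param newdata matrix of descriptors (rows = samples).
#' @param ... unused.
#' @return numeric head probabilities.
#' @export
predict.head_mlp <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  .mlp_forward(object$weights, Xs)$p
}

#' @rdname train_head_classifier
#' @param x a `head_mlp`.
#' @export
glance.head_mlp <- function(x, ...) {
  te <- x$metrics[x$metrics$subset == "test", ]
  tibble(n = sum(x$metrics$n), hidden = ncol(x$weights$W1),
         best_epoch = x$best_epoch, test_accuracy = te$accuracy,
         test_loss = te$loss)
}

#' Classify head candidates
#'
#' Computes HOG descriptors around each candidate circle centre, scores them
#' with the trained classifier, and keeps candidates whose head probability
#' reaches the threshold. Rejected candidates are typically raised arms,
#' balls, or other non-head blobs.
#'
#' @param candidates tibble from [extract_head_candidates()].
#' @param frame grayscale frame the candidates came from.
#' @param classifier a trained `head_mlp`.
#' @param threshold probability threshold in (0, 1].
#' @param hog a [hog_config()].
#' @return tibble of detections: candidate columns plus `score` (the head
#'   probability), filtered to `score >= threshold`.
#' @export
classify_candidates <- function(candidates, frame, classifier,
                                threshold = 0.5, hog = hog_config()) {
  if (nrow(candidates) == 0) {
    return(dplyr::bind_cols(candidates, tibble(score = numeric())))
  }
  feats <- t(vapply(seq_len(nrow(candidates)), function(i) {
    compute_hog(hog_patch(frame, candidates$x[i], candidates$y[i],
                          hog$window), hog)
  }, numeric(hog_length(hog))))
  probs <- predict(classifier, feats)
  out <- dplyr::bind_cols(candidates, tibble(score = probs))
  out[out$score >= threshold, , drop = FALSE]
}

#' Per-camera head detection over an image sequence
#'
#' The full detection stage: adaptive-mixture foreground segmentation with
#' shadow relabeling, morphological cleaning, contour-maxima circle search,
#' interest-area gating, and MLP classification of HOG descriptors.
#'
#' @param frames list of grayscale matrices for one camera.
#' @param camera_id camera index attached to the output.
#' @param classifier trained `head_mlp`, or `NULL` to skip classification
#'   (all circle candidates become detections with `score = NA`).
#' @param interest_area polygon (`x`, `y` columns) or `NULL`.
#' @param bg,hough,hog configuration objects.
#' @param threshold classification threshold.
#' @param kernel_size morphological opening kernel.
#' @return tibble `frame_id` (1-based index into `frames`), `camera_id`,
#'   `x`, `y`, `radius_px`, `score`.
#' @export
detect_heads <- function(frames, camera_id = 0L, classifier = NULL,
                         interest_area = NULL, bg = bg_config(),
                         hough = hough_config(), hog = hog_config(),
                         threshold = 0.5, kernel_size = 3) {
  seg <- segment_foreground(frames, bg)
  out <- list()
  for (i in seq_along(seg$masks)) {
    fid <- seg$frame_ids[i]
    mask <- clean_mask(seg$masks[[i]], kernel_size)
    cand <- extract_head_candidates(mask, frames[[fid]], interest_area, hough)
    det <- if (is.null(classifier)) {
      dplyr::bind_cols(cand, tibble(score = rep(NA_real_, nrow(cand))))
    } else {
      classify_candidates(cand, frames[[fid]], classifier, threshold, hog)
    }
    if (nrow(det)) {
      out[[length(out) + 1]] <-
        dplyr::bind_cols(tibble(frame_id = fid, camera_id = camera_id),
                         det[, c("x", "y", "radius_px", "score")])
    }
  }
  if (!length(out)) {
    return(tibble(frame_id = integer(), camera_id = integer(), x = numeric(),
                  y = numeric(), radius_px = numeric(), score = numeric()))
  }
  dplyr::bind_rows(out)
}
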