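#' Train a small fully connected neural network classifier
#'
#' A dense feed-forward network with two hidden layers (ReLU) and a
#' softmax output, trained by mini-batch gradient descent with momentum on
#' the cross-entropy loss. The learning rate starts at `lr` and is reduced
#' tenfold whenever `patience` consecutive epochs fail to improve the
#' training loss; training stops after two reductions without improvement
#' or at `max_epochs`. Inputs are z-standardized internally (constant
#' columns left at zero).
#'
#' @param x numeric feature matrix (samples x features).
#' @param y factor of class labels.
#' @param hidden integer vector of the two hidden-layer widths.
#' @param lr initial learning rate.
#' @param patience epochs without loss improvement before the rate drops.
#' @param max_epochs training budget.
#' @param batch_size mini-batch size.
#' @param seed integer seed for weight initialization and batching.
#' @return an object of class `vm4_mlp` with a [predict()] method.
#' @export
mlp_train <- function(x, y, hidden = c(64L, 32L), lr = 0.01, patience = 30L,
                      max_epochs = 400L, batch_size = 32L, seed = 1L) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  if (length(classes) < 2L) stop("need at least 2 classes")
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd); scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  n <- nrow(xs); p <- ncol(xs); k <- length(classes)
  yi <- as.integer(y)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), yi)] <- 1

  set.seed(as.integer(seed))
  dims <- c(p, hidden, k)
  W <- lapply(seq_len(3L), function(l)
    matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
           dims[l], dims[l + 1L]))
  b <- lapply(seq_len(3L), function(l) numeric(dims[l + 1L]))
  vW <- lapply(W, function(w) w * 0); vb <- lapply(b, function(bb) bb * 0)
  mom <- 0.9

  forward <- function(xb) {
    a1 <- pmax(sweep(xb %*% W[[1L]], 2L, b[[1L]], "+"), 0)
    a2 <- pmax(sweep(a1 %*% W[[2L]], 2L, b[[2L]], "+"), 0)
    z3 <- sweep(a2 %*% W[[3L]], 2L, b[[3L]], "+")
    z3 <- z3 - apply(z3, 1L, max)
    ez <- exp(z3)
    list(a1 = a1, a2 = a2, prob = ez / rowSums(ez))
  }

  best_loss <- Inf; stall <- 0L; drops <- 0L; rate <- lr
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- xs[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
      fw <- forward(xb)
      d3 <- (fw$prob - yb) / length(idx)
      d2 <- (d3 %*% t(W[[3L]])) * (fw$a2 > 0)
      d1 <- (d2 %*% t(W[[2L]])) * (fw$a1 > 0)
      gW <- list(t(xb) %*% d1, t(fw$a1) %*% d2, t(fw$a2) %*% d3)
      gb <- list(colSums(d1), colSums(d2), colSums(d3))
      for (l in 1:3) {
        vW[[l]] <- mom * vW[[l]] - rate * gW[[l]]
        vb[[l]] <- mom * vb[[l]] - rate * gb[[l]]
        W[[l]] <- W[[l]] + vW[[l]]
        b[[l]] <- b[[l]] + vb[[l]]
      }
    }
    pr <- forward(xs)$prob
    loss <- -mean(log(pmax(pr[cbind(seq_len(n), yi)], 1e-12)))
    if (loss < best_loss - 1e-5) { best_loss <- loss; stall <- 0L }
    else {
      stall <- stall + 1L
      if (stall >= patience) {
        rate <- rate / 10; stall <- 0L; drops <- drops + 1L
        if (drops > 2L) break
      }
    }
  }
  structure(list(W = W, b = b, classes = classes, center = center,
                 scale = scl, hidden = hidden, final_loss = best_loss),
            class = "vm4_mlp")
}

#' @export
predict.vm4_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xb <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L, object$scale, "/")
  a1 <- pmax(sweep(xb %*% object$W[[1L]], 2L, object$b[[1L]], "+"), 0)
  a2 <- pmax(sweep(a1 %*% object$W[[2L]], 2L, object$b[[2L]], "+"), 0)
  z3 <- sweep(a2 %*% object$W[[3L]], 2L, object$b[[3L]], "+")
  z3 <- z3 - apply(z3, 1L, max)
  ez <- exp(z3)
  prob <- ez / rowSums(ez)
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}
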