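# Small trainable semantic head (one hidden layer, sigmoid output) with a
# hand-rolled Adam optimizer: the deep-learning stack is not a dependency,
# and only this head is trained -- the encoder stages act as fixed,
# seeded featurizers.

head_init <- function(d_in, hidden = 16, seed = 1L) {
  rng <- local_rng(seed)
  gauss <- function(nr, nc) rng(function() matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc))
  list(W1 = gauss(hidden, d_in), b1 = rep(0, hidden),
       W2 = gauss(1, hidden), b2 = 0)
}

head_forward <- function(par, X) {
  H <- tanh(X %*% t(par$W1) + matrix(par$b1, nrow(X), length(par$b1), byrow = TRUE))
  z <- as.numeric(H %*% t(par$W2) + par$b2)
  list(prob = stats::plogis(z), H = H)
}

# Class-balanced binary cross-entropy: w gives the per-class weights
# (background, crown), so the scarce background class is not swamped.
head_grad <- function(par, X, y, w = c(1, 1)) {
  fw <- head_forward(par, X)
  n <- nrow(X)
  sw <- ifelse(y == 1, w[2], w[1])
  sw <- sw / sum(sw)
  dz <- (fw$prob - y) * sw                      # weighted BCE + sigmoid
  dW2 <- matrix(dz %*% fw$H, 1)
  db2 <- sum(dz)
  dH <- outer(dz, as.numeric(par$W2)) * (1 - fw$H^2)
  dW1 <- t(dH) %*% X
  db1 <- colSums(dH)
  loss <- -sum(sw * (y * log(pmax(fw$prob, 1e-12)) +
                       (1 - y) * log(pmax(1 - fw$prob, 1e-12))))
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), loss = loss)
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr = 0.01, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                     weight_decay * par[[nm]])
  }
  list(par = par, state = state)
}

#' Count trainable parameters
#'
#' Sums the lengths of all numeric arrays in a (possibly nested) parameter
#' list -- e.g. a single linear layer `list(W = matrix(, 2, 3), b =
#' numeric(2))` counts 8.
#'
#' @param x A parameter list (weights, biases, nested lists thereof).
#' @return Integer parameter count.
#' @export
count_params <- function(x) {
  if (is.numeric(x)) return(length(x))
  if (is.list(x)) return(sum(vapply(x, count_params, 0)))
  0L
}
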