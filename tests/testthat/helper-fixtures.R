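# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

fx_speech <- function() fixture("speech1s", gen_speech_like(1, seed = 7))

fx_noise <- function(class_id = 9L) {
  fixture(paste0("noise", class_id),
          gen_noise(noise_bank()[[class_id + 1L]], 1, seed = 3))
}

# identity-configured denoiser: square layers, W = I, b = 0, so the ReLU path
# is the identity on non-negative inputs
identity_ddae <- function(width = 4L, n_layers = 5L) {
  m <- ddae_init(rep(width, n_layers + 1L), seed = 1)
  for (l in seq_along(m$layers)) {
    m$layers[[l]]$W <- diag(width)
    m$layers[[l]]$b <- numeric(width)
  }
  m
}

# tiny two-class frame sets that are linearly separable
separable_frames <- function(n_per_class = 200L, d = 5L, gap = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * d), ncol = d),
             matrix(stats::rnorm(n_per_class * d, mean = gap), ncol = d))
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

# numerical gradient of a scalar loss in every parameter (central differences)
numerical_grads <- function(model, X, Y, loss, h = 1e-6) {
  lapply(seq_along(model$layers), function(l) {
    gW <- model$layers[[l]]$W * 0
    for (i in seq_along(gW)) {
      mp <- model; mp$layers[[l]]$W[i] <- mp$layers[[l]]$W[i] + h
      mm <- model; mm$layers[[l]]$W[i] <- mm$layers[[l]]$W[i] - h
      gW[i] <- (eanr:::mlp_loss(mp, X, Y, loss) - eanr:::mlp_loss(mm, X, Y, loss)) / (2 * h)
    }
    gb <- model$layers[[l]]$b * 0
    for (i in seq_along(gb)) {
      mp <- model; mp$layers[[l]]$b[i] <- mp$layers[[l]]$b[i] + h
      mm <- model; mm$layers[[l]]$b[i] <- mm$layers[[l]]$b[i] - h
      gb[i] <- (eanr:::mlp_loss(mp, X, Y, loss) - eanr:::mlp_loss(mm, X, Y, loss)) / (2 * h)
    }
    list(W = gW, b = gb)
  })
}

max_rel_err <- function(a, b) {
  max(abs(a - b) / pmax(abs(a) + abs(b), 1e-6))
}
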