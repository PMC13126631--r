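## Neural-network primitives.
##
## The multitask autoencoder is implemented directly on BLAS-backed matrix
## algebra with hand-written reverse-mode gradients (verified against
## finite differences in the test suite). Activations live in (B*T) x D
## matrices: sample b occupies rows [(b-1)*T + 1, b*T], token 1 of each
## sample is the class token. Multi-head attention runs in a compiled
## kernel; everything else is vectorized R.

.addRow <- function(X, b) .cpp_add_bias(X, b)

.linearF <- function(X, W, b) {
  list(out = .cpp_add_bias(X %*% W, b), X = X)
}
.linearB <- function(cache, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

.layernormF <- function(X, g, b) .cpp_layernorm_forward(X, g, b)
.layernormB <- function(cache, g, dY) {
  r <- .cpp_layernorm_backward(cache$xhat, cache$inv, g, dY)
  list(dX = r$dX, dg = as.numeric(r$dg), db = as.numeric(r$db))
}

.geluF <- function(X) .cpp_gelu_forward(X)
.geluB <- function(cache, dY) dY * cache$deriv

## One pre-norm transformer block: x + MHSA(LN(x)), then x + MLP(LN(x)).
## P is the flat parameter list, prefix names this block's tensors.
.blockF <- function(P, prefix, X, B, T, H) {
  D <- ncol(X)
  ln1 <- .layernormF(X, P[[paste0(prefix, ".ln1.g")]], P[[paste0(prefix, ".ln1.b")]])
  qkv <- .linearF(ln1$out, P[[paste0(prefix, ".Wqkv")]], P[[paste0(prefix, ".bqkv")]])
  Q <- qkv$out[, 1:D, drop = FALSE]
  K <- qkv$out[, (D + 1):(2 * D), drop = FALSE]
  V <- qkv$out[, (2 * D + 1):(3 * D), drop = FALSE]
  at <- .cpp_attn_forward(Q, K, V, B, T, H)
  proj <- .linearF(at$out, P[[paste0(prefix, ".Wproj")]], P[[paste0(prefix, ".bproj")]])
  X2 <- X + proj$out
  ln2 <- .layernormF(X2, P[[paste0(prefix, ".ln2.g")]], P[[paste0(prefix, ".ln2.b")]])
  fc1 <- .linearF(ln2$out, P[[paste0(prefix, ".Wfc1")]], P[[paste0(prefix, ".bfc1")]])
  act <- .geluF(fc1$out)
  fc2 <- .linearF(act$out, P[[paste0(prefix, ".Wfc2")]], P[[paste0(prefix, ".bfc2")]])
  out <- X2 + fc2$out
  list(out = out,
       cache = list(ln1 = ln1, qkv = qkv, Q = Q, K = K, V = V, att = at$att,
                    attOut = at$out, proj = proj, ln2 = ln2, fc1 = fc1,
                    act = act, fc2 = fc2, B = B, T = T, H = H))
}

.blockB <- function(P, prefix, cache, dOut, grads) {
  D <- ncol(cache$Q)
  g <- function(n) paste0(prefix, ".", n)
  ## MLP half
  dX2 <- dOut
  l <- .linearB(cache$fc2, P[[g("Wfc2")]], dOut)
  grads[[g("Wfc2")]] <- l$dW; grads[[g("bfc2")]] <- l$db
  dAct <- .geluB(cache$act, l$dX)
  l <- .linearB(cache$fc1, P[[g("Wfc1")]], dAct)
  grads[[g("Wfc1")]] <- l$dW; grads[[g("bfc1")]] <- l$db
  ln <- .layernormB(cache$ln2, P[[g("ln2.g")]], l$dX)
  grads[[g("ln2.g")]] <- ln$dg; grads[[g("ln2.b")]] <- ln$db
  dX2 <- dX2 + ln$dX
  ## attention half
  l <- .linearB(cache$proj, P[[g("Wproj")]], dX2)
  grads[[g("Wproj")]] <- l$dW; grads[[g("bproj")]] <- l$db
  ab <- .cpp_attn_backward(l$dX, cache$Q, cache$K, cache$V, cache$att,
                           cache$B, cache$T, cache$H)
  dQKV <- cbind(ab$dQ, ab$dK, ab$dV)
  l <- .linearB(cache$qkv, P[[g("Wqkv")]], dQKV)
  grads[[g("Wqkv")]] <- l$dW; grads[[g("bqkv")]] <- l$db
  ln <- .layernormB(cache$ln1, P[[g("ln1.g")]], l$dX)
  grads[[g("ln1.g")]] <- ln$dg; grads[[g("ln1.b")]] <- ln$db
  list(dX = dX2 + ln$dX, grads = grads)
}

## Glorot-uniform for weight matrices (keeps activation/gradient variance
## stable through depth); zero biases; unit layer-norm gains.
.glorot <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

.initBlock <- function(P, prefix, D, mlpRatio, rnorm01) {
  P[[paste0(prefix, ".ln1.g")]] <- rep(1, D)
  P[[paste0(prefix, ".ln1.b")]] <- rep(0, D)
  P[[paste0(prefix, ".Wqkv")]] <- .glorot(D, 3 * D)
  P[[paste0(prefix, ".bqkv")]] <- rep(0, 3 * D)
  P[[paste0(prefix, ".Wproj")]] <- .glorot(D, D)
  P[[paste0(prefix, ".bproj")]] <- rep(0, D)
  P[[paste0(prefix, ".ln2.g")]] <- rep(1, D)
  P[[paste0(prefix, ".ln2.b")]] <- rep(0, D)
  P[[paste0(prefix, ".Wfc1")]] <- .glorot(D, mlpRatio * D)
  P[[paste0(prefix, ".bfc1")]] <- rep(0, mlpRatio * D)
  P[[paste0(prefix, ".Wfc2")]] <- .glorot(mlpRatio * D, D)
  P[[paste0(prefix, ".bfc2")]] <- rep(0, D)
  P
}

## Patch bookkeeping: token t of an image covers a patchPx x patchPx square;
## tokens run row-major over the patch grid starting at the bottom-left.
## .patchIndex(cfg)[t, ] gives the flat (column-major) pixel indices of
## token t within the length-npix image vector.
.patchIndex <- function(imagePx, patchPx) {
  nSide <- imagePx %/% patchPx
  idx <- matrix(0L, nSide * nSide, patchPx * patchPx)
  t <- 0L
  for (pr in seq_len(nSide)) for (pc in seq_len(nSide)) {
    t <- t + 1L
    rows <- (pr - 1L) * patchPx + seq_len(patchPx)
    cols <- (pc - 1L) * patchPx + seq_len(patchPx)
    idx[t, ] <- as.integer(outer(rows, (cols - 1L) * imagePx, `+`))
  }
  idx
}

.patchify <- function(Ximg, idxMat) {
  B <- nrow(Ximg)
  p2 <- ncol(idxMat)
  A <- Ximg[, as.vector(t(idxMat)), drop = FALSE]
  matrix(as.vector(t(A)), ncol = p2, byrow = TRUE)
}

.unpatchify <- function(Yt, idxMat, B) {
  p2 <- ncol(idxMat)
  Tn <- nrow(idxMat)
  A <- matrix(as.vector(t(Yt)), nrow = B, byrow = TRUE)  # B x (T*p2)
  out <- matrix(0, B, Tn * p2)
  out[, as.vector(t(idxMat))] <- A
  out
}

## inverse mapping for gradients: image-vector gradient -> token gradient
.patchifyGrad <- function(dXimg, idxMat) .patchify(dXimg, idxMat)
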