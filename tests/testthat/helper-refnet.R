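# R double-precision reference of the CNN forward/backward (tiny dims)
ref_forward_backward <- function(seqs, labs, W, mode, cw, pw=3, ps=2) {
  n <- ncol(seqs); L <- nrow(seqs)
  k1 <- nrow(W$W1)/4; n1 <- ncol(W$W1); k2 <- nrow(W$W2)/n1; n2 <- ncol(W$W2)
  L1 <- L-k1+1; Lp <- (L1-pw)%/%ps+1; L2 <- Lp-k2+1; flat <- L2*n2
  K <- ncol(W$W5)
  sig <- function(x) 1/(1+exp(-x))
  lidx <- function(c,k) if (mode==27) 3*(c-1)+k else if (k==3) 19 else 2*(c-1)+k
  g <- lapply(W, function(w) array(0, dim=dim(w)))
  loss <- 0
  probs <- array(0, c(n, 9, 3))
  for (s in 1:n) {
    X <- matrix(0, L, 4); ok <- seqs[,s] < 4
    X[cbind(which(ok), seqs[ok,s]+1)] <- 1
    P1 <- matrix(0, L1, 4*k1)
    for (k in 0:(k1-1)) P1[, k*4+(1:4)] <- X[(1+k):(L1+k), ]
    Z1 <- sweep(P1 %*% W$W1, 2, -as.vector(W$b1)); H1 <- pmax(Z1, 0)
    Pool <- matrix(0, Lp, n1); argm <- matrix(0L, Lp, n1)
    for (j in 1:Lp) { rows <- ((j-1)*ps+1):((j-1)*ps+pw)
      for (ch in 1:n1) { v <- H1[rows, ch]; a <- which.max(v); Pool[j,ch] <- v[a]; argm[j,ch] <- rows[a] } }
    P2 <- matrix(0, L2, k2*n1)
    for (k in 0:(k2-1)) P2[, k*n1+(1:n1)] <- Pool[(1+k):(L2+k), ]
    Z2 <- sweep(P2 %*% W$W2, 2, -as.vector(W$b2)); H2 <- pmax(Z2, 0)
    xf <- as.vector(H2)
    A3 <- sig(as.vector(xf %*% W$W3) + as.vector(W$b3))
    A4 <- sig(as.vector(A3 %*% W$W4) + as.vector(W$b4))
    Z5 <- as.vector(A4 %*% W$W5) + as.vector(W$b5)
    dZ5 <- numeric(K)
    for (cc in 1:9) {
      z <- sapply(1:3, function(k) Z5[lidx(cc,k)])
      e <- exp(z - max(z)); p <- e/sum(e)
      probs[s, cc, ] <- p
      y <- labs[s, cc] + 1
      loss <- loss + -cw[cc,y]*log(max(p[y],1e-12))
      for (k in 1:3) dZ5[lidx(cc,k)] <- dZ5[lidx(cc,k)] + cw[cc,y]*(p[k]-(k==y))/n
    }
    g$W5 <- g$W5 + outer(A4, dZ5); g$b5 <- g$b5 + dZ5
    dA4 <- as.vector(W$W5 %*% dZ5); dZ4 <- dA4*A4*(1-A4)
    g$W4 <- g$W4 + outer(A3, dZ4); g$b4 <- g$b4 + dZ4
    dA3 <- as.vector(W$W4 %*% dZ4); dZ3 <- dA3*A3*(1-A3)
    g$W3 <- g$W3 + outer(xf, dZ3); g$b3 <- g$b3 + dZ3
    dxf <- as.vector(W$W3 %*% dZ3)
    dH2 <- matrix(dxf, L2, n2); dH2[Z2 <= 0] <- 0
    g$W2 <- g$W2 + t(P2) %*% dH2; g$b2 <- g$b2 + colSums(dH2)
    dP2 <- dH2 %*% t(W$W2)
    dPool <- matrix(0, Lp, n1)
    for (k in 0:(k2-1)) dPool[(1+k):(L2+k), ] <- dPool[(1+k):(L2+k), ] + dP2[, k*n1+(1:n1)]
    dH1 <- matrix(0, L1, n1)
    for (j in 1:Lp) for (ch in 1:n1) dH1[argm[j,ch], ch] <- dH1[argm[j,ch], ch] + dPool[j,ch]
    dH1[Z1 <= 0] <- 0
    g$W1 <- g$W1 + t(P1) %*% dH1; g$b1 <- g$b1 + colSums(dH1)
  }
  list(loss = loss/n, grad = g, probs = probs)
}
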