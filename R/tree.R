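# Binary classification trees for the random forest: fully grown CART
# (Gini) or ID3-style (entropy / information gain) trees with a fresh
# random feature subset evaluated at every node.

# impurity of a vector of positive-class proportions
.impurity_fun <- function(criterion) {
  if (criterion == "gini") {
    function(p) 2 * p * (1 - p)
  } else {
    function(p) {
      out <- numeric(length(p))
      nz <- p > 0 & p < 1
      q <- 1 - p[nz]
      out[nz] <- -(p[nz] * log(p[nz]) + q * log(q))
      out
    }
  }
}

# Grow one tree on (X, y01). Nodes are stored in flat arrays: `sv` is the
# split variable index (NA at leaves), `thr` the threshold (go left when
# x <= thr), `left`/`right` child indices, `prob` the positive-class
# proportion of the node. `importance` accumulates the split's impurity
# decrease weighted by the fraction of samples reaching the node.
.grow_tree <- function(X, y01, mtry, criterion, minsplit = 2,
                       maxdepth = 30) {
  imp_fun <- .impurity_fun(criterion)
  p_feat <- ncol(X)
  n_root <- length(y01)
  sv <- thr <- prob <- numeric(0)
  left <- right <- integer(0)
  imp_acc <- numeric(p_feat)

  build <- function(idx, depth) {
    k <- length(sv) + 1L
    sv[k] <<- NA_real_; thr[k] <<- NA_real_
    left[k] <<- NA_integer_; right[k] <<- NA_integer_
    yy <- y01[idx]
    n <- length(idx)
    pk <- mean(yy)
    prob[k] <<- pk
    if (pk == 0 || pk == 1 || n < minsplit || depth >= maxdepth) return(k)

    feats <- sample.int(p_feat, mtry)
    imp_parent <- imp_fun(pk)
    best_j <- 0L; best_t <- NA_real_; best_dec <- 1e-12
    for (j in feats) {
      xj <- X[idx, j]
      o <- order(xj, method = "radix")
      xs <- xj[o]
      cs <- cumsum(yy[o])
      nl <- seq_len(n - 1)
      valid <- xs[nl] < xs[nl + 1]     # only between distinct values
      if (!any(valid)) next
      pl <- cs[nl] / nl
      pr <- (cs[n] - cs[nl]) / (n - nl)
      dec <- imp_parent - (nl / n) * imp_fun(pl) -
        ((n - nl) / n) * imp_fun(pr)
      dec[!valid] <- -Inf
      mbest <- which.max(dec)
      if (dec[mbest] > best_dec) {
        best_dec <- dec[mbest]
        best_j <- j
        best_t <- (xs[mbest] + xs[mbest + 1]) / 2
      }
    }
    if (best_j == 0L) return(k)   # no impurity-reducing split available

    sv[k] <<- best_j; thr[k] <<- best_t
    imp_acc[best_j] <<- imp_acc[best_j] + (n / n_root) * best_dec
    goleft <- X[idx, best_j] <= best_t
    left[k] <<- build(idx[goleft], depth + 1L)
    right[k] <<- build(idx[!goleft], depth + 1L)
    k
  }
  build(seq_len(n_root), 0L)
  list(sv = sv, thr = thr, left = left, right = right, prob = prob,
       importance = imp_acc)
}

# Route every row of X to its leaf; returns the leaf positive-class
# proportion per row.
.predict_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    active <- which(!is.na(tree$sv[node]))
    if (length(active) == 0) break
    nd <- node[active]
    goleft <- X[cbind(active, as.integer(tree$sv[nd]))] <= tree$thr[nd]
    node[active] <- ifelse(goleft, tree$left[nd], tree$right[nd])
  }
  tree$prob[node]
}
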