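# Adam optimizer over parameter trees (nested lists with numeric leaves),
# with classic L2 weight decay folded into the gradient and bias-corrected
# moment estimates.

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, tspec, eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- tspec$beta1
  b2 <- tspec$beta2
  wd <- tspec$weight_decay
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- vector("list", length(p))
      names(out) <- names(p)
      mm <- out; vv <- out
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        out[[i]] <- r$p; mm[[i]] <- r$m; vv[[i]] <- r$v
      }
      list(p = out, m = mm, v = vv)
    } else {
      g <- g + wd * p
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# Reduce-on-plateau learning-rate schedule with early stopping. Tracks the
# best epoch loss; after `patience` epochs without improvement the rate is
# multiplied by `lr_factor` (floored at `min_lr`); after `early_stop` epochs
# without improvement training stops.
plateau_init <- function(tspec) {
  list(lr = tspec$lr, best = Inf, bad = 0L, stop = FALSE)
}

plateau_update <- function(sched, loss, tspec, rel_tol = 1e-4) {
  if (loss < sched$best * (1 - rel_tol)) {
    sched$best <- loss
    sched$bad <- 0L
  } else {
    sched$bad <- sched$bad + 1L
    if (sched$bad %% tspec$patience == 0L) {
      sched$lr <- max(sched$lr * tspec$lr_factor, tspec$min_lr)
    }
    if (sched$bad >= tspec$early_stop) sched$stop <- TRUE
  }
  sched
}
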