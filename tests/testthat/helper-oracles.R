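# independent oracles kept deliberately separate from the package's own
# solver path

# FBA optimum via pracma's textbook LP (shifted to nonnegative variables);
# returns NULL when pracma does not converge on the instance
pracma_fba_oracle <- function(model, objective, sense = "max") {
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  obj <- numeric(n)
  obj[match(objective, colnames(S))] <- 1
  out <- tryCatch(
    suppressWarnings(pracma::linprog(obj, A = diag(n), b = ub - lb,
                                     Aeq = S, beq = as.numeric(-S %*% lb),
                                     maximize = sense == "max",
                                     maxiter = 5000)),
    error = function(e) NULL)
  if (is.null(out) || out$errno != 1) return(NULL)
  sum(obj * (out$x + lb))
}

# graph-reachability producibility oracle, valid for networks whose
# reactions are irreversible with unit coefficients: a metabolite is
# reachable if some reaction with all substrates reachable produces it;
# exchanges with lb < 0 seed their metabolite
reachability_oracle <- function(model, target) {
  avail <- character(0)
  ex <- model$reactions[model$reactions$kind == "exchange", , drop = FALSE]
  for (i in seq_len(nrow(ex)))
    if (ex$lower_bound[i] < 0) avail <- union(avail, names(ex$stoichiometry[[i]]))
  repeat {
    grew <- FALSE
    for (j in seq_len(nrow(model$reactions))) {
      st <- model$reactions$stoichiometry[[j]]
      if (model$reactions$upper_bound[j] <= 0) next
      subs <- names(st)[st < 0]
      prods <- names(st)[st > 0]
      if (length(prods) && all(subs %in% avail) &&
          !all(prods %in% avail)) {
        avail <- union(avail, prods)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  target %in% avail
}
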