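# Independent oracles used by the unit and acceptance tests.

# scikit-learn PLSRegression (NIPALS, autoscaled) as an external PLSR oracle.
# Batched: `cases` is a list of list(X, y, Xnew, ncomp); one python process
# serves all cases through a temp-file bridge. Returns a list of prediction
# vectors (raw response units).
sklearn_pls_predict <- function(cases) {
  dir <- tempfile("skpls_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    utils::write.table(cs$X, file.path(dir, sprintf("X%d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(cs$y, file.path(dir, sprintf("y%d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(cs$Xnew, file.path(dir, sprintf("Xn%d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    writeLines(as.character(cs$ncomp), file.path(dir, sprintf("k%d.txt", i)))
  }
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.cross_decomposition import PLSRegression",
    "d = sys.argv[1]; n = int(sys.argv[2])",
    "for i in range(1, n + 1):",
    "    X = np.loadtxt(f'{d}/X{i}.csv', delimiter=',', ndmin=2)",
    "    y = np.loadtxt(f'{d}/y{i}.csv', delimiter=',')",
    "    Xn = np.loadtxt(f'{d}/Xn{i}.csv', delimiter=',', ndmin=2)",
    "    k = int(open(f'{d}/k{i}.txt').read())",
    "    m = PLSRegression(n_components=k, scale=True).fit(X, y)",
    "    np.savetxt(f'{d}/pred{i}.csv', m.predict(Xn).ravel())"
  ), script)
  status <- system2("python", c(script, dir, length(cases)),
                    stdout = TRUE, stderr = TRUE)
  lapply(seq_along(cases), function(i) {
    f <- file.path(dir, sprintf("pred%d.csv", i))
    if (!file.exists(f))
      stop("sklearn oracle failed: ", paste(status, collapse = "\n"))
    scan(f, quiet = TRUE)
  })
}

# Brute-force Savitzky-Golay: per-channel truncated-window polynomial
# least-squares fit evaluated at the channel (lm-based).
sg_bruteforce <- function(x, window, polyorder) {
  p <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(p), function(i) {
    win <- max(1L, i - h):min(p, i + h)
    A <- outer(win - i, 0:polyorder, `^`)
    qr.solve(A, x[win])[1]  # fitted value at the centre offset 0
  }, numeric(1))
}

# Brute-force leave-one-out PLSR CV via repeated fit_plsr refits.
loo_cv_bruteforce <- function(X, y, ncomp) {
  n <- nrow(X)
  pred <- vapply(seq_len(n), function(i) {
    fit <- fit_plsr(X[-i, , drop = FALSE], y[-i], ncomp)
    predict(fit, X[i, , drop = FALSE])
  }, numeric(1))
  sqrt(mean((pred - y)^2))
}
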