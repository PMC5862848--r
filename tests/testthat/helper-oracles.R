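# Independent oracles used across the suite. These re-derive the expected
# behaviour by brute force or direct formulas, sharing no code with the
# package implementation.

# brute-force digestion: scan cut sites residue by residue, then
# enumerate every pair of cut boundaries and count the cut sites strictly
# inside the candidate peptide
oracleDigest <- function(sequence, enzymes, maxMissed) {
    res <- strsplit(sequence, "")[[1]]
    n <- length(res)
    cuts <- integer(0)
    if (n >= 2) {
        for (i in 1:(n - 1)) {
            for (e in enzymes) {
                if (res[i] %in% e@cleaveAfter &&
                    !(res[i + 1] %in% e@blockedByNext)) {
                    cuts <- c(cuts, i)
                    break
                }
            }
        }
    }
    b <- c(0L, cuts, n)
    rows <- list()
    for (ii in seq_len(length(b) - 1)) {
        for (jj in (ii + 1):length(b)) {
            internal <- sum(cuts > b[ii] & cuts < b[jj])
            if (internal <= maxMissed)
                rows[[length(rows) + 1L]] <- data.frame(
                    start = b[ii], end = b[jj],
                    sequence = substr(sequence, b[ii] + 1, b[jj]),
                    missed_cleavages = internal)
        }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# exhaustive maximum bipartite matching between theoretical ions and
# observed peaks (each peak usable once), by branch and bound
oracleMatchCount <- function(theo, obs, tol) {
    best <- 0L
    nT <- length(theo)
    rec <- function(ti, used, count) {
        if (count + (nT - ti + 1L) <= best) return(invisible(NULL))
        if (ti > nT) {
            best <<- max(best, count)
            return(invisible(NULL))
        }
        for (oi in seq_along(obs)) {
            if (!used[oi] && abs(theo[ti] - obs[oi]) <= tol) {
                used[oi] <- TRUE
                rec(ti + 1L, used, count + 1L)
                used[oi] <- FALSE
            }
        }
        rec(ti + 1L, used, count)
    }
    rec(1L, logical(length(obs)), 0L)
    best
}

# direct-formula weighted least squares + empirical-Bayes moderation;
# the prior df is found with uniroot rather than Newton iteration
oracleModeratedT <- function(y, w, X, coef = 2) {
    m <- nrow(y)
    n <- ncol(y)
    df <- n - ncol(X)
    beta <- s2 <- u <- numeric(m)
    for (i in seq_len(m)) {
        W <- diag(w[i, ])
        XtWX <- t(X) %*% W %*% X
        b <- solve(XtWX, t(X) %*% W %*% y[i, ])
        r <- y[i, ] - X %*% b
        beta[i] <- b[coef]
        s2[i] <- sum(w[i, ] * r^2) / df
        u[i] <- sqrt(solve(XtWX)[coef, coef])
    }
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- var(e) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
        half <- uniroot(function(x) trigamma(x) - evar,
            c(1e-8, 1e10), extendInt = "downX", tol = 1e-12)$root
        d0 <- 2 * half
        s02 <- exp(mean(e) + digamma(half) - log(half))
        s2post <- (d0 * s02 + df * s2) / (d0 + df)
        dft <- min(d0 + df, m * df)
    } else {
        d0 <- Inf
        s02 <- exp(mean(e))
        s2post <- rep(s02, m)
        dft <- m * df
    }
    t <- beta / (u * sqrt(s2post))
    list(beta = beta, s2 = s2, s2post = s2post, t = t,
        p = 2 * pt(-abs(t), dft), d0 = d0, s02 = s02)
}

# random peptide with a requested number of Cys residues
randomCysPeptide <- function(len, ncys) {
    aa <- setdiff(names(residueMasses()), "C")
    s <- sample(aa, len, replace = TRUE)
    cpos <- sort(sample(len, ncys))
    s[cpos] <- "C"
    list(sequence = paste(s, collapse = ""), cys = cpos)
}

allEnzymes <- function() list(
    trypsin = getEnzyme("trypsin"),
    lysC = getEnzyme("lysC"),
    chymotrypsin = getEnzyme("chymotrypsin"),
    gluC = getEnzyme("gluC"))
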