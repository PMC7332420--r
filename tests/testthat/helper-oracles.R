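## exhaustive change-point search over all cut placements, with the same
## lexicographic tie-break as the implementation (equal segment sizes)
bruteSegments <- function(x, K) {
    x <- as.matrix(x)
    n <- nrow(x)
    segcost <- function(i, j) {
        xs <- x[i:j, , drop = FALSE]
        sum(sweep(xs, 2, colMeans(xs))^2)
    }
    ideal <- n / K
    best <- NULL; bestc <- Inf; bestc2 <- Inf
    cuts <- utils::combn(seq_len(n - 1), K - 1)
    for (k in seq_len(ncol(cuts))) {
        b <- c(cuts[, k], n)
        a <- c(1, head(b, -1) + 1)
        c1 <- sum(mapply(segcost, a, b))
        c2 <- sum((b - a + 1 - ideal)^2)
        tolr <- 1e-9 * (1 + abs(bestc))
        if (c1 < bestc - tolr || (abs(c1 - bestc) <= tolr && c2 < bestc2)) {
            bestc <- min(c1, bestc); bestc2 <- c2; best <- b
        }
    }
    rep(seq_len(K), times = diff(c(0, best)))
}


## independent solution of the same linear system by matrix exponentials:
## x' = A x + b with b piecewise constant over the pulse boundaries; the
## affine step uses the augmented matrix exp([[A, b], [0, 0]]).
expmChase <- function(m, t_max, dt) {
    k <- m@rates; ex <- m@exitRate
    A1 <- diag(-c(k, ex))
    A1[cbind(2:5, 1:4)] <- k
    A <- rbind(cbind(A1, matrix(0, 5, 5)),
               cbind(matrix(0, 5, 5), A1))
    bvec <- function(pulsing) {
        inL <- if (pulsing) m@labelEfficiency * m@entryRate else 0
        c(inL, 0, 0, 0, 0, m@entryRate - inL, 0, 0, 0, 0)
    }
    step <- function(x, b, h) {
        M <- rbind(cbind(A, b), 0)
        E <- as.matrix(Matrix::expm(Matrix::Matrix(M * h)))
        (E %*% c(x, 1))[1:10]
    }
    times <- seq(0, t_max, by = dt)
    out <- matrix(0, length(times), 10)
    x <- c(rep(0, 5), m@init)
    out[1, ] <- x
    for (i in seq_along(times)[-1]) {
        t0 <- times[i - 1]; t1 <- times[i]
        br <- sort(unique(c(t0, pmin(pmax(m@pulseWindow, t0), t1), t1)))
        for (j in seq_len(length(br) - 1)) {
            mid <- (br[j] + br[j + 1]) / 2
            pulsing <- mid >= m@pulseWindow[1] && mid < m@pulseWindow[2]
            x <- step(x, bvec(pulsing), br[j + 1] - br[j])
        }
        out[i, ] <- x
    }
    list(time = times, labelled = out[, 1:5], unlabelled = out[, 6:10])
}

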