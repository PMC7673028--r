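test_that("applyThreshold uses a strict > rule with ties rejected", {
    dt <- applyThreshold(c(a = 0.7, b = 0.5, c = 0.2, d = 0.500001))
    expect_equal(dt$decision, c("ACCEPT", "REJECT", "REJECT", "ACCEPT"))
    expect_equal(dt$trace_id, c("a", "b", "c", "d"))
    empty <- applyThreshold(numeric(0))
    expect_equal(nrow(empty), 0L)
    expect_error(applyThreshold(c(a = 1.2)))
})

test_that("concordance counts agreements and reports vs-manual rates", {
    man <- setNames(rep(c("ACCEPT", "REJECT"), 25), paste0("t", 1:50))
    cr <- concordance(man, man)
    expect_equal(cr$concordance, 1)
    expect_equal(cr$n_agree, 50L)

    pred <- man
    pred["t1"] <- "REJECT"
    cr2 <- concordance(pred, setNames(man[1:10], names(man)[1:10]))
    expect_equal(cr2$concordance, 0.9)

    ## pooled multi-movie concordance equals the weighted per-movie average
    m1 <- setNames(sample(c("ACCEPT", "REJECT"), 30, TRUE), paste0("a", 1:30))
    m2 <- setNames(sample(c("ACCEPT", "REJECT"), 70, TRUE), paste0("b", 1:70))
    p1 <- m1; p1[1:4] <- ifelse(m1[1:4] == "ACCEPT", "REJECT", "ACCEPT")
    p2 <- m2; p2[1:7] <- ifelse(m2[1:7] == "ACCEPT", "REJECT", "ACCEPT")
    pooled <- concordance(c(p1, p2), c(m1, m2))
    per <- c(concordance(p1, m1)$concordance * 30,
             concordance(p2, m2)$concordance * 70) / 100
    expect_equal(pooled$concordance, sum(per))

    ## symmetry in the two label arguments
    expect_equal(concordance(c(p1, p2), c(m1, m2))$concordance,
                 concordance(c(m1, m2), c(p1, p2))$concordance)
    ## invariance to ordering
    shuf <- sample(names(m2))
    expect_equal(concordance(p2[shuf], m2)$concordance,
                 concordance(p2, m2)$concordance)

    expect_error(concordance(p1, c(m1, m2)), class = "smtn_id_mismatch")
})

test_that("frame-level concordance pools all frames incl. rejected traces", {
    pred <- list(a = c(TRUE, TRUE, FALSE, FALSE), b = rep(FALSE, 4))
    man <- list(a = c(TRUE, TRUE, TRUE, FALSE))   # b absent = all-rejected
    cr <- concordance(pred, man, level = "frame")
    expect_equal(cr$n_total, 8L)
    expect_equal(cr$n_agree, 7L)
    expect_equal(cr$concordance, 7 / 8)
})

test_that("rocCurve sweeps thresholds, is monotone, and AUC matches", {
    ## perfectly separated
    s <- c(runif(20, 0.8, 1), runif(20, 0, 0.2))
    lab <- rep(c("ACCEPT", "REJECT"), each = 20)
    r <- rocCurve(s, lab)
    expect_equal(r$auc, 1.0)
    expect_true(all(diff(r$points$sensitivity) >= 0))
    expect_true(all(diff(r$points$fpr) >= 0))

    ## label-independent scores -> AUC ~ 0.5
    set.seed(10)
    s2 <- runif(10000)
    lab2 <- sample(c("ACCEPT", "REJECT"), 10000, TRUE)
    expect_lt(abs(rocCurve(s2, lab2)$auc - 0.5), 0.02)

    ## AUC == normalized Mann-Whitney U statistic (tie-aware oracle)
    set.seed(11)
    s3 <- round(c(rnorm(60, 1), rnorm(40)), 1)   # rounding forces ties
    lab3 <- rep(c("ACCEPT", "REJECT"), c(60, 40))
    w <- stats::wilcox.test(s3[lab3 == "ACCEPT"], s3[lab3 == "REJECT"],
                            exact = FALSE)
    expect_lt(abs(rocCurve(s3, lab3)$auc - w$statistic / (60 * 40)), 1e-9)

    expect_error(rocCurve(s[1:20], lab[1:20]), class = "smtn_single_class")
})

test_that("fretSeries computes clipped proximity ratios conservatively", {
    tr <- rbind(c(0, 500, 1000, -50), c(1000, 500, 0, 20))
    fs <- fretSeries(tr)
    expect_equal(fs$E[1], 1)
    expect_equal(fs$E[2], 0.5)
    expect_equal(fs$E[3], 0)
    expect_true(all(fs$E >= 0 & fs$E <= 1))
    ## dropped + emitted = masked frames (frame 4 has total <= 0)
    expect_equal(length(fs$E) + fs$n_dropped, 4L)

    mask <- c(TRUE, FALSE, TRUE, FALSE)
    fs2 <- fretSeries(tr, mask)
    expect_equal(length(fs2$E) + fs2$n_dropped, 2L)
    expect_error(fretSeries(tr, c(TRUE, FALSE)), class = "smtn_id_mismatch")
    expect_error(fretSeries(tr[1, , drop = FALSE]),
                 class = "smtn_channel_mismatch")
})

test_that("fretSeries recovers the true efficiency mode from simulation", {
    p <- simParams(nFrames = 10000, noiseRange = c(0.05, 0.05))
    set.seed(12)
    E <- 0.7
    sig <- rbind(1000 * (1 - E), 1000 * E)[, rep(1, 10000)] +
        matrix(rnorm(20000, 0, 50), nrow = 2)
    fs <- fretSeries(sig)
    h <- hist(fs$E, breaks = seq(0, 1, by = 0.02), plot = FALSE)
    ## histogram mode falls in a bin touching the true efficiency 0.7
    expect_lt(abs(h$mids[which.max(h$counts)] - 0.7), 0.02)
})

test_that("fitTwoGaussians recovers mixture parameters and flags degeneracy", {
    set.seed(13)
    E <- c(rnorm(12000, 0.3, 0.05), rnorm(8000, 0.7, 0.05))
    E <- E[E >= 0 & E <= 1]
    gf <- fitTwoGaussians(E)
    expect_lt(abs(gf$mean[1] - 0.3), 0.02)
    expect_lt(abs(gf$mean[2] - 0.7), 0.02)
    expect_lt(abs(gf$population[1] - 0.6), 0.03)
    expect_equal(sum(gf$population), 1)
    expect_true(gf$mean[1] < gf$mean[2])   # canonical order
    expect_false(gf$degenerate)

    ## all mass at one value -> degenerate, one component absorbs ~100%
    gf2 <- fitTwoGaussians(rep(0.5, 500) + rnorm(500, 0, 1e-3))
    expect_true(gf2$degenerate)
    expect_gt(max(gf2$population), 0.9)
})

test_that("kineticSummary idealizes telegraph traces exactly when noiseless", {
    x <- rep(0, 600)
    for (st in c(100, 250, 400)) x[st:(st + 49)] <- 1000
    ks <- kineticSummary(matrix(x, nrow = 1))
    expect_equal(ks$n_bind_dissociate, 6L)
    expect_equal(ks$tau_bound, 50)
    expect_equal(ks$tau_bound_s, 5)

    flat <- kineticSummary(rep(3, 100) + rnorm(100, 0, 1e-6))
    expect_equal(flat$n_bind_dissociate, 0L)
    expect_true(is.na(flat$tau_bound))
})

test_that("kineticSummary recovers simulated dwell times within 10%", {
    p <- simrepsParams(nFrames = 3000, kOn = 0.02, kOff = 0.02,
                       noiseRange = c(0.1, 0.1))
    ts <- simulateSimreps("MUT", 300, p, seed = 14)
    dwells <- unlist(lapply(seq_len(300), function(i) {
        ks <- kineticSummary(intensities(ts, i))
        ks$tau_bound
    }))
    pooled <- mean(dwells, na.rm = TRUE)
    expect_lt(abs(pooled - 50) / 50, 0.10)
})
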