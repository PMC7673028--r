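test_that("delimited dialect round-trips intensities bit-for-bit", {
    ts <- tinyFretSet(3, T = 50)
    f <- withr::local_tempfile(fileext = ".csv")
    writeTraceTable(ts, f, "delimited")
    back <- readTraceTable(f, "delimited")
    expect_equal(traceIDs(back), traceIDs(ts))
    for (i in 1:3)
        expect_identical(unname(intensities(back, i)),
                         unname(intensities(ts, i)))
    expect_equal(unique(nChannels(back)), 2L)
})

test_that("container dialect round-trips traces, ids and movie grouping", {
    ts <- c(tinyFretSet(3, T = 40, seed = 1),
            simulateSimreps("MUT", 2, simrepsParams(nFrames = 40), seed = 2))
    f <- withr::local_tempfile(fileext = ".trc")
    ## container groups by movie but must preserve global order
    expect_error(writeTraceTable(ts, f, "container"), NA)
    back <- readTraceTable(f, "container")
    expect_equal(traceIDs(back), traceIDs(ts))
    for (i in seq_len(nTraces(ts)))
        expect_identical(unname(intensities(back, i)),
                         unname(intensities(ts, i)))
    expect_equal(traceData(back)$movieID, traceData(ts)$movieID)
})

test_that("a 10,000-trace simulation fits one container file and rereads fully", {
    ts <- simulateAcceptedFret(10000, simParams(nFrames = 30), seed = 3)
    f <- withr::local_tempfile()
    writeTraceTable(ts, f, "container")
    expect_equal(nTraces(readTraceTable(f, "container")), 10000L)
})

test_that("delimited parser infers channels and reports bad cells by line", {
    f <- withr::local_tempfile(fileext = ".csv")
    ## 3-column file (frame, donor, acceptor) without trace_id -> one
    ## 2-channel trace named after the file
    writeLines(c("frame,donor,acceptor",
                 paste(0:299, rnorm(300, 800), rnorm(300, 200), sep = ",")),
               f)
    ts <- readTraceTable(f, "delimited")
    expect_equal(nTraces(ts), 1L)
    expect_equal(unname(traceLengths(ts)), 300L)
    expect_equal(unname(nChannels(ts)), 2L)

    ## corrupt one cell: the error must name the file line
    lines <- readLines(f)
    lines[17] <- "15,oops,42.0"
    writeLines(lines, f)
    err <- tryCatch(readTraceTable(f, "delimited"), error = identity)
    expect_s3_class(err, "smtn_parse")
    expect_match(conditionMessage(err), "line 17")

    ## mixed channel counts in one long file -> format error
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("trace_id,frame,donor,acceptor",
                 "a,0,1,2", "a,1,2,3", "b,0,5,", "b,1,6,"), f2)
    expect_error(readTraceTable(f2, "delimited"), class = "smtn_format")
})

test_that("writing refuses an empty TraceSet", {
    empty <- TraceSet(list())
    f <- withr::local_tempfile()
    expect_error(writeTraceTable(empty, f, "delimited"),
                 class = "smtn_empty")
    expect_error(writeTraceTable(empty, f, "container"),
                 class = "smtn_empty")
    expect_false(file.exists(f))
})

test_that("label files round-trip and reject unknown tokens", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("trace_id,accept_reject,mask",
                 "t1,ACCEPT,0:400", "t2,REJECT,"), f)
    lab <- readLabels(f)
    expect_equal(nrow(lab), 2L)
    expect_equal(lab$label, c("ACCEPT", "REJECT"))
    expect_equal(S4Vectors::metadata(lab)$scheme, "accept_reject")
    m <- maskFromSpec(lab$mask[1], 600)
    expect_equal(sum(m), 400L)
    expect_true(all(m[1:400]) && !any(m[401:600]))
    expect_identical(maskFromSpec(lab$mask[2], 10), rep(FALSE, 10))

    writeLines(c("trace_id,accept_reject", "t1,MAYBE"), f)
    err <- tryCatch(readLabels(f), error = identity)
    expect_s3_class(err, "smtn_bad_label")
    expect_match(conditionMessage(err), "ACCEPT, REJECT")

    f2 <- withr::local_tempfile(fileext = ".csv")
    labs <- data.frame(trace_id = c("a", "b"), label = c("MUT", "WT"),
                       mask = c(maskToSpec(c(TRUE, TRUE, FALSE)), ""))
    writeLabels(labs, f2, "mut_wt")
    back <- readLabels(f2)
    expect_equal(back$label, c("MUT", "WT"))
    expect_identical(maskFromSpec(back$mask[1], 3), c(TRUE, TRUE, FALSE))
})

test_that("mask specs parse runs, 0/1 strings and reject malformed input", {
    expect_identical(maskFromSpec("0:2;4:5", 6),
                     c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
    expect_identical(maskFromSpec("0110", 4), c(FALSE, TRUE, TRUE, FALSE))
    expect_error(maskFromSpec("0110", 5), class = "smtn_parse")
    expect_error(maskFromSpec("5:2", 10), class = "smtn_parse")
    m <- c(FALSE, TRUE, TRUE, FALSE, TRUE)
    expect_identical(maskFromSpec(maskToSpec(m), 5), m)
})
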