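## hand-built placements: one pair, mate spans chosen explicitly
mk_placement <- function(id, ref, r1, r2) {
  data.frame(read_id = id, ref = ref,
             fragStart = min(r1[1], r2[1]), fragStop = max(r1[2], r2[2]),
             strand = "+", r1Start = r1[1], r1Stop = r1[2],
             r2Start = r2[1], r2Stop = r2[2], stringsAsFactors = FALSE)
}

## one integration with configurable junction intervals
mk_int <- function(int_start = 100L, int_stop = 200L, lenL = 0L, lenR = 0L,
                   hpos = 100L, host_del = 0L) {
  data.frame(
    id = 0L, chr = "chrA", hPos = hpos, hostDeleted = host_del,
    virus = "v", virusStart = 0L, virusStop = int_stop - int_start,
    fragmentStructure = sprintf("0-%d+", int_stop - int_start),
    whole = TRUE, rearrangement = FALSE, deletion = FALSE, numFragments = 1L,
    juncTypesLeft = if (lenL > 0) "gap" else "clean",
    juncTypesRight = if (lenR > 0) "gap" else "clean",
    juncLenLeft = lenL, juncLenRight = lenR,
    juncBasesLeft = "", juncBasesRight = "",
    intStart = int_start, intStop = int_stop, stringsAsFactors = FALSE
  )
}

test_that("junction points carry the modified interval and host coordinate", {
  ints <- mk_int(int_start = 100L, int_stop = 200L, lenL = 5L, lenR = 0L,
                 hpos = 90L, host_del = 7L)
  jx <- junction_points(ints)
  expect_equal(nrow(jx), 2L)
  left <- jx[jx$side == "left", ]
  right <- jx[jx$side == "right", ]
  expect_equal(c(left$mod_start, left$mod_stop), c(100L, 105L))
  expect_equal(c(right$mod_start, right$mod_stop), c(200L, 200L))
  expect_equal(left$host_pos, 90L)
  expect_equal(right$host_pos, 97L)  # hPos + hostDeleted
})

test_that("chimeric support requires full coverage of the interval plus flank", {
  ints <- mk_int()              # clean junctions at 100 and 200
  jx <- junction_points(ints)
  ## no reads at all
  none <- find_chimeric(mk_placement("r", "chrA", c(400, 420), c(500, 520))[0, ],
                        jx, 1)
  expect_true(all(lengths(none) == 0L))
  ## clean junction at 100, span [90,110): supports with min_flank 1
  pl <- mk_placement("r1", "chrA", c(90, 110), c(400, 420))
  ch <- find_chimeric(pl, jx, 1)
  expect_equal(ch[["0:left"]], "r1/1")
  expect_length(ch[["0:right"]], 0L)
  ## wrong chromosome: no support
  ch2 <- find_chimeric(mk_placement("r2", "chrB", c(90, 110), c(400, 420)), jx, 1)
  expect_length(ch2[["0:left"]], 0L)
  ## min_flank respected: span touching the breakpoint exactly does not cross
  ch3 <- find_chimeric(mk_placement("r3", "chrA", c(100, 120), c(400, 420)), jx, 1)
  expect_length(ch3[["0:left"]], 0L)
  ## larger flank requirement
  ch4 <- find_chimeric(pl, jx, 20)
  expect_length(ch4[["0:left"]], 0L)
})

test_that("a gap junction needs flank beyond the ambiguous interval", {
  ints <- mk_int(lenL = 5L)     # gap interval [100,105)
  jx <- junction_points(ints)
  ## read span [97,105): covers the interval but no flank right of it
  ch <- find_chimeric(mk_placement("g1", "chrA", c(97, 105), c(400, 420)), jx, 1)
  expect_length(ch[["0:left"]], 0L)
  ## span [97,106): one base either side -> supports
  ch2 <- find_chimeric(mk_placement("g2", "chrA", c(97, 106), c(400, 420)), jx, 1)
  expect_equal(ch2[["0:left"]], "g2/1")
})

test_that("discordant pairs need one host mate and one virus mate, not chimeric", {
  ints <- mk_int()              # inserted span [100,200)
  ## both mates inside the virus span: not discordant
  d1 <- find_discordant(mk_placement("p1", "chrA", c(110, 140), c(150, 180)),
                        ints, 1)
  expect_length(d1[["0"]], 0L)
  ## r1 wholly left of the insertion, r2 wholly inside: discordant
  d2 <- find_discordant(mk_placement("p2", "chrA", c(10, 40), c(150, 180)),
                        ints, 1)
  expect_equal(d2[["0"]], "p2")
  ## r1 crosses the left junction: excluded even though r2 is inside
  d3 <- find_discordant(mk_placement("p3", "chrA", c(90, 110), c(150, 180)),
                        ints, 1)
  expect_length(d3[["0"]], 0L)
  ## both mates in host: not discordant
  d4 <- find_discordant(mk_placement("p4", "chrA", c(10, 40), c(300, 330)),
                        ints, 1)
  expect_length(d4[["0"]], 0L)
})

test_that("annotation appends id lists and self-consistent counts", {
  ints <- mk_int()
  jx <- junction_points(ints)
  ## empty support: zero counts, original columns untouched
  ann0 <- annotate_int_info(ints, find_chimeric(mk_placement("x", "chrA",
                                                             c(0, 10), c(20, 30))[0, ],
                                                jx, 1))
  expect_equal(ann0$nLeft, 0L)
  expect_equal(ann0$leftReads, "")
  expect_identical(ann0[, names(ints)], ints)

  pl <- rbind(mk_placement("a", "chrA", c(90, 110), c(400, 420)),
              mk_placement("b", "chrA", c(95, 115), c(400, 420)),
              mk_placement("c", "chrA", c(190, 210), c(400, 420)))
  ch <- find_chimeric(pl, jx, 1)
  di <- find_discordant(pl, ints, 1)
  ann <- annotate_int_info(ints, ch, di)
  expect_equal(ann$nLeft, 2L)
  expect_equal(sort(strsplit(ann$leftReads, ";")[[1]]), c("a/1", "b/1"))
  expect_equal(ann$nRight, 1L)
  ## counts always match the id lists
  expect_equal(ann$nLeft, lengths(strsplit(ann$leftReads, ";")))
  expect_equal(ann$nDiscordant,
               ifelse(ann$discordantPairs == "", 0L,
                      lengths(strsplit(ann$discordantPairs, ";"))))
  ## unknown id in support is an error
  bad <- ch
  names(bad)[1] <- "99:left"
  expect_error(annotate_int_info(ints, bad), "unknown")
})

test_that("BED output lists supported junctions as sorted 1 bp host features", {
  ints <- rbind(mk_int(), mk_int())
  ints$id <- 0:1
  ints$hPos <- c(5000L, 1234L)
  ints$intStart <- c(100L, 5300L); ints$intStop <- c(200L, 5400L)
  jx <- junction_points(ints)
  pl <- rbind(mk_placement("a", "chrA", c(5290, 5310), c(20, 40)),   # left of int 1
              mk_placement("b", "chrA", c(90, 110), c(20, 40)))     # left of int 0
  ch <- find_chimeric(pl, jx, 1)
  path <- withr::local_tempfile(fileext = ".bed")
  write_supported_bed(jx, ch, path)
  lines <- readLines(path)
  expect_equal(lines, c("chrA\t1234\t1235", "chrA\t5000\t5001"))  # sorted
  ## no supported junctions -> empty file
  path0 <- withr::local_tempfile(fileext = ".bed")
  write_supported_bed(jx, find_chimeric(pl[0, ], jx, 1), path0)
  expect_equal(length(readLines(path0)), 0L)
})

test_that("with deep error-free coverage nearly every junction is supported", {
  fix <- tiny_refs(host_len = 30000, virus_len = 800)
  p <- tiny_params(n_ints = 8, min_sep = 2000, coverage = 10,
                   error_rate_start = 0, error_rate_end = 0)
  sim <- simulate_integrations(fix$host, fix$virus, p, seed = 31)
  pl <- plan_fragments(sim$reference, p)
  jx <- junction_points(sim$integrations)
  ch <- find_chimeric(pl, jx, 1)
  frac <- mean(vapply(ch, length, integer(1)) > 0L)
  expect_gte(frac, 0.95)
  ## BED line count bounded by 2 x integrations
  path <- withr::local_tempfile(fileext = ".bed")
  write_supported_bed(jx, ch, path)
  expect_lte(length(readLines(path)), 2L * nrow(sim$integrations))
  ## annotation is a pure function of its inputs
  a1 <- annotate_int_info(sim$integrations, ch, find_discordant(pl, sim$integrations, 1))
  a2 <- annotate_int_info(sim$integrations, ch, find_discordant(pl, sim$integrations, 1))
  expect_identical(a1, a2)
})

test_that("SAM placements produce the same annotation as the native table", {
  skip_if_not_installed("Rsamtools")
  fix <- tiny_refs(host_len = 5000, virus_len = 300)
  p <- tiny_params(n_ints = 2, min_sep = 500, coverage = 3, read_len = 50,
                   frag_mean = 150, frag_sd = 10)
  sim <- simulate_integrations(fix$host, fix$virus, p, seed = 32)
  pl <- plan_fragments(sim$reference, p)
  ## write a minimal name-sorted SAM equivalent of the placements
  sam <- withr::local_tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:queryname",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sim$reference),
                   nchar(sim$reference)))
  recs <- character(0)
  for (i in seq_len(nrow(pl))) {
    flag1 <- 64L + 1L + 2L
    flag2 <- 128L + 1L + 2L
    if (pl$strand[i] == "-") { flag1 <- flag1 + 16L } else { flag2 <- flag2 + 16L }
    seq1 <- strrep("A", p$read_len)
    recs <- c(recs,
              sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t0\t%s\t*",
                      pl$read_id[i], flag1, pl$ref[i], pl$r1Start[i] + 1L,
                      p$read_len, pl$r2Start[i] + 1L, seq1),
              sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t0\t%s\t*",
                      pl$read_id[i], flag2, pl$ref[i], pl$r2Start[i] + 1L,
                      p$read_len, pl$r1Start[i] + 1L, seq1))
  }
  writeLines(c(hdr, recs), sam)
  from_sam <- read_placements_sam(sam)
  from_sam <- from_sam[order(from_sam$read_id), ]
  native <- pl[order(pl$read_id), ]
  expect_setequal(from_sam$read_id, native$read_id)
  expect_equal(from_sam$r1Start, native$r1Start)
  expect_equal(from_sam$r2Start, native$r2Start)
  jx <- junction_points(sim$integrations)
  expect_identical(
    find_chimeric(from_sam[order(match(from_sam$read_id, pl$read_id)), ], jx, 1),
    find_chimeric(pl, jx, 1))
})
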