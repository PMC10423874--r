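toy_complex <- function(seed = 1, gap = 12, n = 40) {
  synthesize_complex(list(list(n = n, sigmas = c(5, 4, 3), mode = "ideal_micelle"),
                          list(n = n, sigmas = c(5, 4, 3), mode = "mixed")),
                     gap = gap, seed = seed)
}

test_that("in-context status of the full complex equals the individual fit", {
  cx <- toy_complex()
  all_sel <- residue_selection("all", chain = c("A", "B"), kind = "custom")
  a <- status_individual(cx, mode = "complex")
  b <- status_in_context(cx, all_sel, mode = "complex")
  expect_equal(b$status, a$status)
  expect_equal(b$profile$T, a$profile$T)
  expect_equal(b$profile$O, a$profile$O)
})

test_that("in-context restriction equals hand-sliced, renormalised vectors", {
  cx <- toy_complex(seed = 4)
  whole <- fod(cx)
  selB <- residue_selection("chain B", chain = "B", kind = "chain")
  ctx <- status_in_context(cx, selB)
  idx <- which(cx$residues$chain == "B")
  Ts <- whole$profile$T[idx] / sum(whole$profile$T[idx])
  Os <- whole$profile$O[idx] / sum(whole$profile$O[idx])
  expect_equal(ctx$profile$T, Ts, tolerance = 1e-12)
  expect_equal(ctx$profile$O, Os, tolerance = 1e-12)
  d_ot <- brute_kl(Os, Ts); d_or <- brute_kl(Os, rep(1 / length(idx), length(idx)))
  expect_equal(ctx$status$rd, d_ot / (d_ot + d_or), tolerance = 1e-9)
  expect_equal(ctx$status$mode, "chain_in_complex")
  # the in-context fit differs from the chain fitted as its own unit
  ind <- status_individual(subset_chains(cx, "B"))
  expect_false(isTRUE(all.equal(ind$status$rd, ctx$status$rd)))
})

test_that("interface selection equals the brute-force all-pairs scan", {
  cx <- toy_complex(seed = 7, gap = 10)
  sel <- interface_selection(cx, cutoff = 9)
  expect_setequal(sel$idx, brute_interface(cx, 9))
  expect_gt(length(sel$idx), 0)
  # monotone: shrinks as the cutoff decreases
  s6 <- interface_selection(cx, cutoff = 6)
  s3 <- interface_selection(cx, cutoff = 3)
  expect_true(all(s6$idx %in% sel$idx))
  expect_true(all(s3$idx %in% s6$idx))
  # chains separated beyond the cutoff -> empty selection
  apart <- toy_complex(seed = 7, gap = 80)
  expect_length(interface_selection(apart, cutoff = 9)$idx, 0)
  # single chain is an error
  expect_error(interface_selection(subset_chains(cx, "A")), "two chains")
})

test_that("interface selection is symmetric for a mirrored dimer", {
  a <- synthesize_unit(n = 30, seed = 5, sigmas = c(5, 4, 3), mode = "mixed")
  b <- a
  b$residues$chain <- "B"
  b$residues$x <- 16 - b$residues$x
  b$atoms$x <- 16 - b$atoms$x
  cx <- structure_unit(rbind(a$residues, b$residues),
                       rbind(a$atoms, transform(b$atoms, res_idx = res_idx + 30)),
                       source = "mirror")
  sel <- interface_selection(cx, cutoff = 9)
  ia <- sel$idx[sel$idx <= 30]
  ib <- sel$idx[sel$idx > 30] - 30
  expect_setequal(ia, ib)
  fa <- fod(cx, residue_selection("A", chain = "A"), mode = "chain_in_complex")
  fb <- fod(cx, residue_selection("B", chain = "B"), mode = "chain_in_complex")
  expect_equal(fa$status$rd, fb$status$rd, tolerance = 1e-9)
})

test_that("SS-bond fragments become contiguous selections", {
  u <- synthesize_unit(n = 40, seed = 12, sigmas = c(7, 6, 5),
                       mode = "ideal_micelle")
  expect_length(ss_fragment_selections(u), 0)
  u2 <- synthesize_unit(n = 40, seed = 12, sigmas = c(7, 6, 5),
                        mode = "ideal_micelle", n_ss_bonds = 3)
  sels <- ss_fragment_selections(u2)
  expect_length(sels, 3)
  b <- u2$ss_bonds
  for (i in seq_along(sels)) {
    expect_equal(sels[[i]]$idx,
                 seq(match(b$resno1[i], u2$residues$resno),
                     match(b$resno2[i], u2$residues$resno)))
    expect_equal(sels[[i]]$kind, "ss_fragment")
  }
  # inter-chain bond skipped with a warning
  cx <- toy_complex(seed = 2)
  cx$residues$aa[c(1, 41)] <- "CYS"
  cx$ss_bonds <- data.frame(chain1 = "A", resno1 = 1, icode1 = "",
                            chain2 = "B", resno2 = 1, icode2 = "")
  expect_warning(out <- ss_fragment_selections(cx), "inter-chain")
  expect_length(out, 0)
})

test_that("cross-form status maps bound interface onto the unbound form", {
  cx <- toy_complex(seed = 9, gap = 10)
  bound_fit <- fod(cx)
  sel <- interface_selection(cx, cutoff = 9)
  # identical structures: cross-form equals the bound fragment status
  direct <- fragment_status(bound_fit, sel$idx)
  cross <- cross_form_status(bound_fit, bound_fit, sel)
  expect_equal(cross$status$rd, direct$status$rd)
  expect_equal(cross$status$k_opt, direct$status$k_opt)
  expect_equal(cross$status$mode, "cross_form")
  # renumbered unbound copy with an explicit offset mapping
  unbound <- subset_chains(cx, "A")
  ufit <- fod(unbound)
  shifted <- unbound
  shifted$residues$resno <- shifted$residues$resno + 10
  sfit <- fod(shifted)
  selA <- residue_selection("ifaceA", keys = cx$residues[
    sel$idx[cx$residues$chain[sel$idx] == "A"], c("chain", "resno", "icode")])
  viaShift <- cross_form_status(sfit, bound_fit, selA, offsets = c(A = 10))
  direct2 <- cross_form_status(ufit, bound_fit, selA)
  expect_equal(viaShift$status$rd, direct2$status$rd, tolerance = 1e-12)
  # unmapped residues are listed
  expect_error(cross_form_status(sfit, bound_fit, selA), "no unbound")
})

test_that("selections resolve ranges, keys and chains consistently", {
  cx <- toy_complex(seed = 3)
  sel <- residue_selection("rng", chain = "A", from = 5, to = 9)
  expect_equal(oildrop:::selection_indices(sel, cx), 5:9)
  sel2 <- residue_selection("keys", keys = data.frame(chain = "B",
                                                      resno = c(2, 4)))
  expect_equal(oildrop:::selection_indices(sel2, cx), c(42, 44))
  expect_error(oildrop:::selection_indices(
    residue_selection("bad", keys = data.frame(chain = "Z", resno = 1)), cx),
    "absent")
  expect_error(oildrop:::selection_indices(
    residue_selection("none", chain = "A", from = 900, to = 990), cx),
    "no residues")
})

test_that("selections round-trip through a YAML config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("- name: dom1", "  kind: domain", "  chain: A",
               "  from: 3", "  to: 12",
               "- name: whole_B", "  kind: chain", "  chain: B"), path)
  sels <- read_selections(path)
  expect_length(sels, 2)
  expect_equal(sels[[1]]$name, "dom1")
  expect_equal(sels[[1]]$kind, "domain")
  cx <- toy_complex(seed = 3)
  expect_equal(oildrop:::selection_indices(sels[[1]], cx), 3:12)
  expect_equal(oildrop:::selection_indices(sels[[2]], cx), 41:80)
})
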