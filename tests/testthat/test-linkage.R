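mk_keys <- function(id, cnes = "1000001", dob = as.Date("1990-01-01"),
                    admission = as.Date("2021-11-03"),
                    discharge = as.Date("2021-11-05"),
                    race = "1", postcode = "01000000") {
  data.frame(id = id, cnes = cnes, dob = as.Date(dob),
             admission_date = as.Date(admission),
             discharge_date = as.Date(discharge),
             race_color = race, postcode = postcode,
             stringsAsFactors = FALSE)
}

test_that("pass structure: exact first, then progressively relaxed keys", {
  eps <- rbind(
    mk_keys("E1"),                                         # all six agree
    mk_keys("E2", dob = "1991-01-01", postcode = NA),      # postcode missing
    mk_keys("E3", dob = "1992-01-01", postcode = NA, race = NA),
    mk_keys("E4", dob = "1993-01-01", postcode = NA, race = NA,
            discharge = "2021-11-06")                      # discharge off by 1
  )
  ref <- rbind(
    mk_keys("R1"),
    mk_keys("R2", dob = "1991-01-01"),
    mk_keys("R3", dob = "1992-01-01"),
    mk_keys("R4", dob = "1993-01-01")
  )
  res <- deterministic_link(eps, ref)
  pairs <- res$pairs[order(res$pairs$episode_id), ]
  expect_equal(pairs$episode_id, c("E1", "E2", "E3", "E4"))
  expect_equal(pairs$reference_id, c("R1", "R2", "R3", "R4"))
  expect_equal(pairs$pass, 1:4)
  expect_equal(res$ambiguity_count, 0L)
})

test_that("missing key values never satisfy equality", {
  eps <- mk_keys("E1", dob = NA)
  ref <- mk_keys("R1", dob = NA)
  res <- deterministic_link(eps, ref)
  expect_equal(nrow(res$pairs), 0L)   # dob is required in every pass
})

test_that("ambiguous key blocks are left unmatched and counted", {
  eps <- rbind(mk_keys("E1"), mk_keys("E2"))  # identical keys
  ref <- mk_keys("R1")
  res <- deterministic_link(eps, ref)
  expect_equal(nrow(res$pairs), 0L)
  expect_setequal(res$unmatched_episodes, c("E1", "E2"))
  expect_equal(res$unmatched_reference, "R1")
  expect_gte(res$ambiguity_count, 1L)
})

test_that("duplicate ids are rejected and empty reference links nothing", {
  eps <- mk_keys("E1")
  expect_error(deterministic_link(eps, rbind(mk_keys("R1"), mk_keys("R1"))),
               "duplicate")
  res <- deterministic_link(eps, mk_keys("R1")[0, ])
  expect_equal(nrow(res$pairs), 0L)
})

test_that("linkage is one-to-one and pass-monotone under key corruption", {
  set.seed(99)
  n <- 200
  ref <- mk_keys(sprintf("R%03d", 1:n),
                 dob = as.Date("1980-01-01") + sample(0:5000, n),
                 admission = as.Date("2021-11-01") + sample(0:29, n, TRUE),
                 race = sample(c("1", "3"), n, TRUE),
                 postcode = sprintf("%08d", sample.int(1e6, n)))
  ref$discharge_date <- ref$admission_date + sample(1:4, n, TRUE)
  eps <- ref
  eps$id <- sprintf("E%03d", 1:n)
  # corrupt 10% of postcodes and 5% of discharge dates by one day
  hit <- sample(n, n * 0.10)
  eps$postcode[hit] <- sprintf("%08d", sample.int(1e6, length(hit)))
  hit2 <- sample(n, n * 0.05)
  eps$discharge_date[hit2] <- eps$discharge_date[hit2] + 1

  res <- deterministic_link(eps, ref)
  expect_equal(anyDuplicated(res$pairs$episode_id), 0)
  expect_equal(anyDuplicated(res$pairs$reference_id), 0)
  rep_full <- link_report(res)
  expect_lte(rep_full$matched, n)
  expect_gt(rep_full$matched, 0.9 * n)  # relaxation passes recover corruption

  # truncating the pass list never increases the number of matches
  for (k in 1:3) {
    res_k <- deterministic_link(eps, ref,
                                passes = default_link_passes()[1:k])
    expect_lte(nrow(res_k$pairs), nrow(res$pairs))
    # matched pairs are correct where keys were unique by construction
    m <- merge(res_k$pairs, res$pairs, by = "episode_id")
    expect_equal(m$reference_id.x, m$reference_id.y)
  }
})

test_that("clean unique keys recover the ground-truth pairing exactly", {
  sim <- simulate_claims(zero_noise_config(101, 3, 2, 40))
  res <- run_pipeline(sim$reference, sim$reduced, sim$acts)
  truth <- sim$truth$pairing
  morb <- rowSums(sim$truth$flags) > 0
  expect_equal(nrow(res$link$pairs), sum(morb))
  # every linked pair joins the episode whose first AIH the generator billed
  ep <- res$episodes$episodes
  first_aih <- ep$first_aih[match(res$link$pairs$episode_id, ep$episode_id)]
  expect_equal(first_aih,
               truth$first_aih[match(res$link$pairs$reference_id,
                                     truth$reference_id)])
})
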