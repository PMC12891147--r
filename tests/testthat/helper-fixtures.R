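# Deterministic fixture cohorts embedding known count pairs, built in code.
# Spine configurations are chosen so that the OLVF metrics partition exactly:
#   {T7: -3}              most severe -3,  OLVFss -3
#   {T7: -2.5}            most severe -2.5, OLVFss -2.5
#   {T7: -2}              most severe -2,   OLVFss -2 (not <= -2.5)
#   {T7: -1.5}            most severe -1.5, OLVFss -1.5
#   {T5: -1.5, T9: -1.5}  most severe -1.5, OLVFss -3 (sum without adjacency)

.fx_subject <- function(id, sex, fn, ls, fx_time = 2, death_time = NA_real_) {
  data.frame(subject_id = id, sex = sex, age_years = 80, fn_tscore = fn,
             ls_tscore = ls, hip_fx = TRUE, fx_time_years = fx_time,
             death_time_years = death_time, followup_years = 5,
             stringsAsFactors = FALSE)
}

.ctrl_subject <- function(id, sex, fn, ls, death_time = NA_real_) {
  data.frame(subject_id = id, sex = sex, age_years = 72, fn_tscore = fn,
             ls_tscore = ls, hip_fx = FALSE, fx_time_years = NA_real_,
             death_time_years = death_time, followup_years = 5,
             stringsAsFactors = FALSE)
}

# women: 2000 enrolled, 50 deaths (one after a year-2 fracture), 1951 analysed,
# 26 hip Fx; FN<=-2.7 positives 326 (17 Fx), LS<=-3.7 positives 283 (10 Fx,
# one Fx case missing LS), most-severe -3 92 (7 Fx), exactly -2.5 67 (3 Fx),
# remaining OLVFss<=-1.5 via a single -1.5 vertebra (total 277 positive, 14 Fx)
fixture_cohort_women <- function() {
  fn_pos <- -3.0; fn_neg <- -1.0; ls_pos <- -3.8; ls_neg <- -1.0
  n_fx <- 26
  fx <- do.call(rbind, lapply(seq_len(n_fx), function(i) {
    .fx_subject(sprintf("WF%03d", i), "female",
                fn = if (i <= 17) fn_pos else fn_neg,
                ls = if (i == 1) NA_real_ else if (i <= 11) ls_pos else ls_neg,
                death_time = if (i == 26) 3 else NA_real_)
  }))
  # controls: 309 FN+, 273 LS+, spines 85 x(-3), 64 x(-2.5), 114 x(-1.5),
  # 49 deaths (year 2), rest plain survivors; totals 2000 subjects
  n_ctrl <- 2000 - n_fx
  ctrl <- do.call(rbind, lapply(seq_len(n_ctrl), function(i) {
    .ctrl_subject(sprintf("WC%04d", i), "female",
                  fn = if (i <= 309) fn_pos else fn_neg,
                  ls = if (i <= 273) ls_pos else ls_neg,
                  death_time = if (i > n_ctrl - 49) 2 else NA_real_)
  }))
  subjects <- rbind(fx, ctrl)
  spine_of <- function(ids, score) {
    data.frame(subject_id = ids, level = "T7", score = score,
               stringsAsFactors = FALSE)
  }
  vert <- rbind(
    spine_of(fx$subject_id[1:7], -3),          # 7 Fx collapsed
    spine_of(fx$subject_id[8:10], -2.5),       # 3 Fx severe
    spine_of(fx$subject_id[11:14], -1.5),      # 4 Fx moderate
    spine_of(ctrl$subject_id[1:85], -3),
    spine_of(ctrl$subject_id[86:149], -2.5),
    spine_of(ctrl$subject_id[150:263], -1.5)
  )
  structure(list(subjects = subjects, vertebrae = vert, config = NULL),
            class = "olvf_cohort")
}

# men: 2000 enrolled, 121 deaths (three after fracture), 1882 analysed, 23 hip
# Fx within 5 years of which 8 within 3 years; FN<=-2.1 positives 283 (12 Fx,
# 6 of the 8 early Fx), LS<=-2.5 positives 200 (9 Fx, 5 of the early 8);
# OLVFss<=-2.5 positives 104 (5 Fx), most-severe<=-2.0 positives 87 (4 Fx),
# overlap via -2.5 spines, olvfss-only via paired -1.5 spines, hi-only via -2
fixture_cohort_men <- function() {
  fn_pos <- -2.5; fn_neg <- -1.0; ls_pos <- -2.8; ls_neg <- -1.0
  n_fx <- 23
  # first 8 fracture within 3 years; FN+ for 6 of them and 6 of the late 15;
  # LS+ for 5 early and 4 late
  fn_flag <- c(rep(TRUE, 6), FALSE, FALSE, rep(TRUE, 6), rep(FALSE, 9))
  ls_flag <- c(rep(TRUE, 5), rep(FALSE, 3), rep(TRUE, 4), rep(FALSE, 11))
  fx_time <- c(1, 2, 2, rep(2.5, 5), rep(4, 15))
  death <- c(2.5, 3, 3.5, rep(NA_real_, 20))
  fx <- do.call(rbind, lapply(seq_len(n_fx), function(i) {
    .fx_subject(sprintf("MF%03d", i), "male",
                fn = if (fn_flag[i]) fn_pos else fn_neg,
                ls = if (ls_flag[i]) ls_pos else ls_neg,
                fx_time = fx_time[i], death_time = death[i])
  }))
  n_ctrl <- 2000 - n_fx
  ctrl <- do.call(rbind, lapply(seq_len(n_ctrl), function(i) {
    .ctrl_subject(sprintf("MC%04d", i), "male",
                  fn = if (i <= 271) fn_pos else fn_neg,
                  ls = if (i <= 191) ls_pos else ls_neg,
                  death_time = if (i > n_ctrl - 118) 3.5 else NA_real_)
  }))
  subjects <- rbind(fx, ctrl)
  one_level <- function(ids, score) {
    data.frame(subject_id = ids, level = "T7", score = score,
               stringsAsFactors = FALSE)
  }
  two_level <- function(ids) {
    rbind(data.frame(subject_id = ids, level = "T5", score = -1.5,
                     stringsAsFactors = FALSE),
          data.frame(subject_id = ids, level = "T9", score = -1.5,
                     stringsAsFactors = FALSE))
  }
  # Fx spines: 3 in both groups (-2.5), 2 olvfss-only, 1 hi-only
  vert <- rbind(
    one_level(fx$subject_id[1:3], -2.5),
    two_level(fx$subject_id[4:5]),
    one_level(fx$subject_id[6], -2),
    # controls: both 57 x(-2.5); olvfss-only 42 (paired -1.5); hi-only 26 (-2)
    one_level(ctrl$subject_id[1:57], -2.5),
    two_level(ctrl$subject_id[58:99]),
    one_level(ctrl$subject_id[100:125], -2)
  )
  structure(list(subjects = subjects, vertebrae = vert, config = NULL),
            class = "olvf_cohort")
}
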