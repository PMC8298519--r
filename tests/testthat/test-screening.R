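# build a feature table directly from a design (screening consumes the
# feature_table contract, not raw segments)
ft_from_design <- function(values, experience, task) {
  n <- length(values)
  df <- data.frame(segment_id = sprintf("s%04d", 1:n),
                   case_id = "case_01", task = task,
                   surgeon_id = ifelse(experience == "Expert", "S01", "S02"),
                   experience = experience, stringsAsFactors = FALSE)
  for (f in FEATURE_CATALOGUE) df[[f]] <- values
  class(df) <- c("feature_table", "data.frame")
  df
}

test_that("two-way ANOVA detects a pure experience effect in a balanced design", {
  set.seed(12)
  # 2 x 2 balanced cells, means 0,0 (Expert) vs 1,1 (Novice), sd 0.1
  experience <- rep(c("Expert", "Novice"), each = 40)
  task <- rep(rep(c("Pulling", "Coagulation"), each = 20), 2)
  mu <- ifelse(experience == "Novice", 1, 0)
  ft <- ft_from_design(mu + rnorm(80, 0, 0.1), experience, task)
  rep <- anova_screen(ft)
  row <- rep$rows[rep$rows$feature == "max", ]
  expect_lt(row$p_experience, 0.001)
  expect_gt(row$p_task, 0.05)
  expect_equal(row$n_used, 80L)
})

test_that("Type II F statistics match from-scratch RSS differences on an unbalanced layout", {
  set.seed(23)
  n <- c(35, 12, 20, 8)   # unbalanced 2x2
  experience <- rep(c("Expert", "Expert", "Novice", "Novice"), n)
  task <- rep(c("Pulling", "Coagulation", "Pulling", "Coagulation"), n)
  v <- rnorm(sum(n)) + (experience == "Novice") * 0.8 +
    (task == "Pulling") * 0.3
  ft <- ft_from_design(v, experience, task)
  row <- anova_screen(ft)$rows[1, ]

  E <- factor(experience); Tk <- factor(task)
  rss <- function(f) sum(residuals(f)^2)
  full <- lm(v ~ E * Tk)
  both <- lm(v ~ E + Tk)
  ssE <- rss(lm(v ~ Tk)) - rss(both)
  ssT <- rss(lm(v ~ E)) - rss(both)
  ssI <- rss(both) - rss(full)
  dfres <- df.residual(full)
  msres <- rss(full) / dfres
  expect_equal(row$f_experience, (ssE / 1) / msres, tolerance = 1e-8)
  expect_equal(row$f_task, (ssT / 1) / msres, tolerance = 1e-8)
  expect_equal(row$f_interaction, (ssI / 1) / msres, tolerance = 1e-8)
  expect_equal(row$p_experience, pf((ssE / 1) / msres, 1, dfres,
                                    lower.tail = FALSE), tolerance = 1e-8)
})

test_that("degenerate inputs are handled without crashing", {
  ft <- ft_from_design(rep(1, 40), rep(c("Expert", "Novice"), 20),
                       rep(c("Pulling", "Coagulation"), each = 20))
  rep <- anova_screen(ft)
  expect_true(all(is.na(rep$rows$p_experience)))

  ft1 <- ft_from_design(rnorm(40), rep("Expert", 40),
                        rep(c("Pulling", "Coagulation"), each = 20))
  expect_error(anova_screen(ft1), "configuration error")
})

test_that("post-hoc task contrasts are Tukey-adjusted pairwise differences", {
  set.seed(33)
  n_per <- 30
  task <- rep(TASK_LEVELS, each = n_per)
  v <- rnorm(length(task))
  ft <- ft_from_design(v, rep(c("Expert", "Novice"), length.out = length(v)),
                       task)
  ph <- posthoc_tasks(ft, "mean")
  expect_equal(nrow(ph), choose(5, 2))
  # differences equal direct group-mean subtraction
  for (i in seq_len(nrow(ph))) {
    pair <- strsplit(ph$contrast[i], "-", fixed = TRUE)[[1]]
    expect_equal(ph$difference[i],
                 mean(v[task == pair[1]]) - mean(v[task == pair[2]]),
                 tolerance = 1e-10)
  }
})

test_that("null task contrasts rarely reach significance", {
  set.seed(44)
  hits <- 0L
  for (r in 1:100) {
    v <- rnorm(60)
    ft <- ft_from_design(v, rep(c("Expert", "Novice"), 30),
                         rep(c("Pulling", "Coagulation"), each = 30))
    ph <- posthoc_tasks(ft, "mean")
    if (all(ph$p_adj > 0.05)) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("the fixed subset rule removes the 12 listed features leaving 25", {
  sel <- select_model_subset(mode = "fixed")
  expect_length(sel, 25L)
  expect_length(FIXED_EXCLUDED_FEATURES, 12L)
  expect_false(any(FIXED_EXCLUDED_FEATURES %in% sel))
  expect_setequal(c(sel, FIXED_EXCLUDED_FEATURES), FEATURE_CATALOGUE)
  # idempotent under re-application
  expect_identical(intersect(sel, select_model_subset(mode = "fixed")), sel)
})

test_that("threshold selection with alpha 1 keeps the whole catalogue", {
  set.seed(55)
  ft <- ft_from_design(rnorm(40), rep(c("Expert", "Novice"), 20),
                       rep(c("Pulling", "Coagulation"), each = 20))
  rep <- anova_screen(ft)
  expect_length(select_model_subset(rep, mode = "threshold", alpha = 1.0),
                37L)
  expect_error(select_model_subset(rep, mode = "everything"),
               "should be one of")
})
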