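# Closed-loop flavour-preference training cohorts.

# The four counterbalanced groups: which flavour is trained first and which
# flavour is paired with water (rehydrating) vs 600 mM NaCl (dehydrating).
TRAINING_GROUPS <- list(
  `1` = list(first = "grape", map = c(grape = "NaCl_600mM", lime = "water")),
  `2` = list(first = "lime",  map = c(grape = "NaCl_600mM", lime = "water")),
  `3` = list(first = "grape", map = c(grape = "water", lime = "NaCl_600mM")),
  `4` = list(first = "lime",  map = c(grape = "water", lime = "NaCl_600mM"))
)

#' Simulate a closed-loop flavour-preference training cohort
#'
#' Emulates the ten-day protocol: a two-day two-bottle preference test, six
#' days of single-bottle training in which every lick of a flavoured solution
#' triggers a 1 ul intragastric infusion of its mapped solution (water for one
#' flavour, hypertonic saline for the other; three days per flavour, order and
#' mapping counterbalanced over four groups), then a second two-day two-bottle
#' test. Bottle side is randomized on the first day of each test and reversed
#' on the second.
#'
#' Learning model: each mouse starts with a latent probability \code{p0} of
#' choosing the water-paired flavour (drawn around \code{p0_mean}); after
#' training this becomes \code{p_post = p0 + drift * (1 - p0)}. During
#' training, daily lick counts drift linearly from \code{licks_per_day} on day
#' 1 of a block to \code{licks_per_day * (1 + drift * consumption_gain)} (water
#' pairing) or \code{* (1 - drift * consumption_gain)} (saline pairing) on day
#' 3.
#'
#' @param n_per_group mice per counterbalanced group (4 groups).
#' @param learning list: \code{p0_mean} (0.5), \code{p0_sd} (0.05),
#'   \code{drift} in \code{[0, 1]} (0.8), \code{consumption_gain} (0.5),
#'   \code{licks_per_test} (500), \code{licks_per_day} (600),
#'   \code{deterministic} — if TRUE, lick counts are expectations rather than
#'   binomial/Poisson draws.
#' @param seed integer seed.
#' @return a list of class \code{training_dataset}: \code{mice}, a list with
#'   per-mouse \code{group}, \code{map}, \code{pre}/\code{post} two-bottle
#'   tests (per-day lick counts per flavour and bottle side), and
#'   \code{training}, a data.frame of per-day lick counts, flavours, and
#'   infused solutions/volumes. Ground truth (p0, p_post per mouse) is in
#'   attribute \code{"truth"}.
#' @export
gen_training_cohort <- function(n_per_group = 3, learning = list(),
                                seed = 1L) {
  if (n_per_group < 1) stop("need at least one mouse per group")
  p <- utils::modifyList(
    list(p0_mean = 0.5, p0_sd = 0.05, drift = 0.8, consumption_gain = 0.5,
         licks_per_test = 500, licks_per_day = 600, deterministic = FALSE),
    learning)
  if (p$drift < 0 || p$drift > 1) stop("`drift` must be in [0, 1]")

  mice <- list()
  truth <- list()
  mid <- 0L
  for (g in names(TRAINING_GROUPS)) {
    grp <- TRAINING_GROUPS[[g]]
    water_flavour <- names(grp$map)[grp$map == "water"]
    for (k in seq_len(n_per_group)) {
      mid <- mid + 1L
      mouse_id <- sprintf("m%02d", mid)
      mouse <- with_substream(seed, paste0("mouse/", mouse_id), {
        p0 <- min(max(rnorm(1, p$p0_mean, p$p0_sd), 0.01), 0.99)
        p_post <- p0 + p$drift * (1 - p0)
        pre <- two_bottle_test(p0, water_flavour, p$licks_per_test,
                               p$deterministic)
        post <- two_bottle_test(p_post, water_flavour, p$licks_per_test,
                                p$deterministic)
        # six training days: 3 with the first flavour, 3 with the second
        flavours <- c(rep(grp$first, 3),
                      rep(setdiff(names(grp$map), grp$first), 3))
        train <- do.call(rbind, lapply(1:6, function(day) {
          fl <- flavours[day]
          block_day <- ((day - 1) %% 3) + 1
          gain <- if (grp$map[[fl]] == "water") p$consumption_gain else
            -p$consumption_gain
          mu <- p$licks_per_day *
            (1 + gain * p$drift * (block_day - 1) / 2)
          mu <- max(mu, 0)
          licks <- if (p$deterministic) round(mu) else rpois(1, mu)
          data.frame(day = day, flavour = fl,
                     infused = unname(grp$map[[fl]]),
                     licks = licks, infused_ul = licks * 1,
                     stringsAsFactors = FALSE)
        }))
        list(p0 = p0, p_post = p_post, pre = pre, post = post,
             training = train)
      })
      mice[[mouse_id]] <- list(mouse_id = mouse_id, group = as.integer(g),
                               map = grp$map, first = grp$first,
                               pre = mouse$pre, post = mouse$post,
                               training = mouse$training)
      truth[[mouse_id]] <- data.frame(mouse_id = mouse_id,
                                      group = as.integer(g),
                                      water_flavour = water_flavour,
                                      p0 = mouse$p0, p_post = mouse$p_post,
                                      stringsAsFactors = FALSE)
    }
  }
  ds <- structure(list(mice = mice), class = "training_dataset")
  attr(ds, "truth") <- do.call(rbind, truth)
  attr(ds, "learning") <- p
  ds
}

# One two-bottle test (two days, side randomized then reversed). p_wp is the
# per-lick probability of choosing the water-paired flavour.
two_bottle_test <- function(p_wp, water_flavour, licks_per_day,
                            deterministic) {
  side1 <- sample(c("front", "back"), 1)
  other <- setdiff(c("grape", "lime"), water_flavour)
  days <- lapply(1:2, function(day) {
    wp_licks <- if (deterministic) round(licks_per_day * p_wp) else
      rbinom(1, licks_per_day, p_wp)
    data.frame(day = day,
               flavour = c(water_flavour, other),
               licks = c(wp_licks, licks_per_day - wp_licks),
               side = if (day == 1) c(side1, setdiff(c("front", "back"), side1))
                      else c(setdiff(c("front", "back"), side1), side1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, days)
}

#' @export
print.training_dataset <- function(x, ...) {
  cat(sprintf("<training_dataset> %d mice, 4 groups, 2+6+2 day protocol\n",
              length(x$mice)))
  invisible(x)
}
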