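# entrainr

Multi-timescale analysis of collective attention entrainment: tools for
time-locking a timestamped social-media message stream to an annotated
broadcast conversation (e.g. a televised political debate) and modelling
how the per-second rate of messages mentioning the participants follows
the event's structure.

Audiences watching a massively shared event comment on it in real time.
`entrainr` quantifies that coupling at three timescales:

1. **Interactional (seconds).** When a speaker takes or holds the floor,
   mentions of that speaker rise within seconds. Per-second mention
   counts are modelled with linear mixed-effects models (REML, `lme4`)
   with fixed effects *speaker*, *speaking time* and their interaction
   (and, in a second model, *interruption*), random intercepts and
   slopes by speech turn, standardized coefficients, Satterthwaite
   p-values, and marginal/conditional R² (variance explained by fixed
   effects alone vs. fixed plus random).
2. **Content (minutes).** A pointed remark ("meme") triggers a burst
   that is partially self-sustaining. The per-second rate of messages
   containing the remark's key term, time-locked to its onset, is
   modelled as a novelty decay coupled to an adoption sigmoid:

   N(t) = e^(−λt),  M(t) = 1 / (1 + e^(−m(t−s))),  model(t) = M(t)·[N(t) − b]

   with λ the decay rate (1/s), s the time of maximal uptake (s), m the
   uptake slope (1/s), and b the base rate estimated from the final
   100 s of the window. Parameters are chosen by exhaustive grid search
   maximising the Pearson correlation with the observed series (plus an
   optional local refinement); the correlation objective makes the fit
   invariant to positive affine rescaling of the data.
3. **Event-level (the whole broadcast).** Overall attention rises after
   onset and decays toward the end: an OLS regression of the total rate
   on standardized linear and quadratic time, plus a decay-only test on
   the second half of the event.

A combined multiscale regression assembles all three timescales (with
their pairwise interactions) into one per-second OLS model of the total
rate, decomposes R² into the unique (semi-partial) contribution of each
block by entering it last, and transfers the fitted coefficients to a
second event to test generalisation.

Because raw platform streams are typically not redistributable, the
package ships a synthetic generator (`generate_debate()`,
`generate_messages()`) that simulates an annotated debate and an
entrained Poisson message stream with known ground truth — speaker
boosts, interruption boosts, speaking-time slopes, a quadratic trend,
burst-decay meme kernels, retweets and URL spam — so that every pipeline
stage is testable end to end.

## Worked example

```r
library(entrainr)

# a synthetic 90-minute debate with one salient remark at t = 1800 s
sim   <- simulate_event(debate_config(seed = 3), generative_truth(seed = 4))
spec  <- filter_spec(c(candidates(sim$annotation), "keyword"))
rates <- align_and_bin(filter_messages(sim$messages, spec), sim$annotation)
rates
#> Rate series: 5400 bins of 1 s from t0 = 0 s
#>   candidate_a  sum 37077, peak 24
#>   candidate_b  sum 38921, peak 26
#>   keyword      sum 785, peak 10
#>   total        sum 75998, peak 39

design <- build_turn_design(sim$annotation, rates, "candidate_a")
fit_speaker_model(design)
#> Linear mixed model of count_target (standardized) (n = 5400)
#>           term   beta t_value p_value
#>    (Intercept) -0.361   -9.32 7.5e-18
#>        speaker  1.159   18.61 1.0e-48
#>          stime -0.100   -5.12 3.2e-07
#>  speaker:stime  0.453   15.05 3.6e-50
#> R2 marginal = 0.352, conditional = 0.519
#> note: random slopes dropped (fallback to random intercept)

w <- event_locked_window(rates, onset_s = 1800, post_s = 700)
fit_meme(w, "keyword")
#> Salient-event (decay x sigmoid) fit
#>   lambda = 0.007197 /s, m = 0.2952 /s, s = 58.65 s, b = 0
#>   r = 0.7925 (R2 = 0.6281) on 600 bins; 38125 grid evaluations + local refinement

fit_quadratic_trend(rates)
#> Quadratic long-term trend (n = 5400 bins)
#>   linear:    beta = -0.157, t = -11.67, p = 4.07e-31
#>   quadratic: beta = -0.056, t = -4.14, p = 3.46e-05
#>   R2 = 0.028
#>   second-half decay alone: beta = -0.096, t = -5.03, p = 5.28e-07
```

Reading the output: the speaking candidate's mention rate is strongly
elevated while he holds the floor (standardized speaker β = 1.16,
t = 18.6) and grows the longer the turn lasts (positive
speaker × speaking-time interaction); the salient remark's burst decays
at λ ≈ 0.007/s with maximal uptake near s ≈ 59 s after the remark
(the generating kernel used λ = 0.01, s = 60); and total attention
declines significantly over the event with a negative quadratic
component. `build_multiscale_design()` + `fit_multiscale()` combine the
three scales, and `transfer_predict()` applies a fitted model to a
second event.

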