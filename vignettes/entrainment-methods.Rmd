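---
title: "Modelling collective attention entrainment at three timescales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling collective attention entrainment at three timescales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(entrainr)
```

## The problem

When millions of people watch the same broadcast conversation — the
canonical case is a televised two-candidate political debate with a
moderator — many of them comment on it in real time on social media.
The per-second rate of messages mentioning each participant is then a
large-scale behavioural signal that can be time-locked, second by
second, to the annotated structure of the conversation itself.
`entrainr` implements that time-locking and a set of models for the
coupling ("entrainment") at three timescales: turn-taking dynamics,
salient-remark ("meme") bursts, and the slow rise and decay of
attention over the whole event.

The pipeline is: read or simulate a conversational annotation (speech
turns with start/end times and interruption flags, plus salient-event
onsets and their key terms); read or simulate a timestamped message
stream; filter the stream (term matching, URL and retweet exclusion);
bin matching messages into per-second counts aligned to the event
onset; and fit the timescale models to the resulting rate series.

## Filtering and binning

Messages are assigned to a term channel when the lowercased text
contains the term as a substring. This deliberately does not require
word boundaries, so `"#obama2012"` matches the term `"obama"`:
hashtags are part of the text and platform tagging conventions glue
terms together. A uniform substring rule for text and hashtag is a
design choice — the alternative (exact tag equality for hashtags)
would miss the very common *term-plus-suffix* tags.

Two exclusion filters address contaminants. Messages containing
`http://`, `https://` or `www.` are dropped as likely spam-bot output;
messages flagged as retweets (platform metadata where available, the
conventional `"RT @"` prefix otherwise) are dropped so that rate
patterns are not generated by verbatim repetition of one message.

Bins are half-open intervals $[k, k+1)$ seconds from event onset
(0-based); a message at absolute time $\tau$ lands in bin
$\lfloor \tau - \text{onset} \rfloor$. Messages outside
$[0, \text{duration})$ are dropped and counted in a log. The `total`
channel counts each message once, however many term channels it
matched. Missing values (e.g. empty bins in a mention-proportion
ratio) are propagated as `NA`, never silently zero-filled.

**Floor resolution.** Interruptions make turns overlap, but per-second
covariates need a unique floor-holder. The rule is *last starter
wins*: at time $t$ the floor belongs to the turn with the latest start
$\le t$ that has not yet ended. This mirrors interruption semantics —
the interrupter seizes the floor at their start, and the floor reverts
to the interrupted turn if it outlasts the interruption. Two turns
with identical starts are rejected at validation, since the rule would
be ambiguous. Moderator seconds remain in the timeline and are coded
as "no candidate speaking" in candidate-centric designs.

## Timescale 1: turn-taking and interruptions

Per-second counts within speech turns are modelled with Gaussian
linear mixed models (REML, `lme4`):

* **Speaker model** — response: standardized per-second mentions of
  one candidate; fixed effects: `speaker` (that candidate holds the
  floor), standardized `speaking time` (seconds into the current
  turn), and their interaction. One model is fitted per candidate
  channel.
* **Interruption model** — response: standardized total rate; fixed
  effects: `interruption` (the floor-holding turn began as an
  interruption), `speaking time`, interaction.

Both include a random intercept and *uncorrelated* random slopes for
the dichotomous factor and speaking time, grouped by turn. The
uncorrelated (`||`) parameterisation is a deliberate choice: with
turn-constant factors the full covariance is weakly identified and
frequently fails to converge. When even the reduced structure fails or
is singular, the model falls back to a random intercept only and flags
the result (`fallback = TRUE`). A *boundary* (zero-variance) fit of
the fallback is reported with `singular = TRUE` rather than as an
error: on data with genuinely no turn-to-turn heterogeneity — e.g. a
homogeneous Poisson stream — a zero variance estimate is the correct
answer, and the fixed effects remain valid.

Continuous variables (response and speaking time) are z-scored before
fitting, so coefficients are standardized betas and invariant to the
units of raw time. P-values use the Satterthwaite degrees-of-freedom
approximation (`lmerTest`). Marginal and conditional R² follow the
Nakagawa–Schielzeth decomposition,
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)$ and
$R^2_c = (\sigma^2_f + \sigma^2_r) / (\cdot)$, with the random-slope
contribution averaged over the observed covariates (Johnson's
extension), computed directly from the `lme4` variance components in
`r2_mixed()`.

The response is a count but the model is Gaussian. That mismatch is
intentional and mirrors standard practice for high-rate per-second
data; the synthetic generator (below) produces genuinely Poisson
counts precisely so that the tests measure how the Gaussian
approximation behaves, and the recovery tolerances account for it.

## Timescale 2: salient events

A salient remark produces a burst whose novelty decays,
$N(t) = e^{-\lambda t}$, while social uptake sustains it as a meme,
$M(t) = 1/(1 + e^{-m(t-s)})$: $s$ (seconds) is where uptake rises
fastest, $m$ (1/s) its slope. The fitted curve is the product
$M(t)\,[N(t) - b]$ with $b$ the base rate, by default the mean of the
final 100 s of the fitted window.

As printed, this composite tends to $-b$ for large $t$ while an
observed rate tends to $+b$. Whether the intended form was
$M\cdot N - b$ cannot be settled from the functional description
alone; we implement the printed product form because the fitting
objective — Pearson correlation between model and data — is invariant
to positive affine maps of either series, making the offset (and any
max-scaling of the data for display) immaterial to the fitted
$\lambda, m, s$. That invariance is asserted exactly in the tests.

Fitting is an exhaustive grid search; default ranges are
$\lambda \in [10^{-4}, 0.1]$ 1/s (25 log-spaced; half-lives from ~2 h
down to 7 s), $m \in [0.01, 1]$ 1/s (25 log-spaced), $s \in [0, 300]$ s
(5-s steps), all overridable via `meme_grid()`. Exact ties break
toward the smallest $\lambda$, then smallest $s$, then smallest $m$
(the least dramatic kinetics). A Nelder–Mead refinement starts at the
grid optimum and is kept only if it strictly improves the correlation;
it frees the estimates from the grid resolution (the λ grid steps by
×1.33, coarser than the ±20% recovery the tests demand). The fit
window is 600 s after onset — such bursts fade over roughly ten
minutes — and is configurable.

## Timescale 3: the whole event

Total rate is regressed on standardized centred time and its square.
Centring before squaring, then z-scoring both terms and the response,
tames the $t$/$t^2$ collinearity and puts betas on the standardized
scale. An inverted-U course appears as a negative quadratic beta. The
*second-half decay test* restricts to bins in the second half of the
event — where an inverted U has only its falling limb — and regresses
the count on the centred quadratic term alone (centred about the
full-series midpoint, with an intercept): a significantly negative
coefficient shows the late decay is not an artefact of the early rise.

## The combined multiscale model

One OLS model per event predicts the total per-second rate from all
timescales: standardized `t_lin`/`t_quad`; `speak_time` (seconds into
the current turn while *any* candidate speaks) plus a candidate
indicator `cand_a`; an `interrupt` indicator; and `salient`, the
summed fitted composite kernel value at each second (zero outside
kernel windows). The per-candidate vs. any-candidate coding of
"speaker duration" is genuinely open; we use any-candidate speaking
time plus one candidate indicator, which keeps the design full-rank
and transfers across events whose candidates differ. Pairwise
products among the primary covariates (`speak_time`, `interrupt`,
`t_lin`, `salient`) are included; each interaction belongs to both
parents' blocks.

The unique contribution of a block is its semi-partial R²:
$R^2(\text{full}) - R^2(\text{full minus the block and every
interaction involving it})$ — the gain from entering it last. By
nesting this is nonnegative up to numerical tolerance; the tests
verify it against an exhaustive leave-one-block-out oracle.

**Transfer.** To test generalisation, the model fitted on one event
(without the salient block — salient events are identified post hoc
and do not generalise) is applied to a second event's covariates, and
the Pearson correlation between predicted and observed counts is
reported. The source event's standardization statistics are reused
when building the target design, so the coefficients apply on the
same scale. Applied to its own data the transfer correlation equals
$\sqrt{R^2}$ exactly, which the tests assert. Significance is
reported at p < 0.05 with no multiplicity correction, matching the
reporting convention of the analyses this package operationalises.

## The synthetic generator

Raw platform streams are generally not redistributable, so the
generator is a first-class module: it defines the study conditions
under which every claim in the test suite is evaluated.

The timeline generator alternates candidate turns with moderator
interjections (probability 0.25), log-normal turn durations (mean
25 s, log-SD 0.9 — a heavy right tail, as real turn annotations show
durations from under a second to minutes), and marks each non-initial
turn as an interruption with probability 0.54, in which case it starts
up to 2 s before the previous turn ends. Duration defaults to 5400 s.
These values are anchored to the descriptive statistics of annotated
televised debates (about 200 turns and half of them interruptions in
90 minutes).

The stream generator draws per-second Poisson counts per candidate
channel with log rate

    base + [own turn]·log(speaker_boost)
         + own/cross speaking-time slopes
         + [interrupting turn]·log(interruption_boost)
         + q1·x + q2·x²            (x = t/duration)
         + Σ active kernels: amplitude · M(t−onset) · N(t−onset)

Counts are Poisson with a log link *on purpose*: the analysis models
are Gaussian approximations of integer data, and parameter-recovery
tolerances are set with that mismatch in mind. Kernel-induced messages
are drawn separately (the channel's kernel-free count at the rate
without the kernel term, the kernel-attributed excess at the
difference) and only the excess messages carry the kernel's match
term: messages *about the remark mention the remark*, so the filtered
term channel follows the kernel's burst-decay shape while the total
stream follows the full log-linear rate. Speaking-time effects end
with the turn; there is no carry-over.

Defaults: base rate 10 messages/s per channel, speaker boost 1.5,
speaking-time slopes ±0.004 /s, interruption boost 1.5, quadratic
coefficients (0.3, −0.5) on normalised time (attention peaks 30% into
the event and declines thereafter), one kernel (λ = 0.01, m = 0.2,
s = 60, amplitude 1), retweet fraction 0.53 (roughly half of debate
traffic is retweets), URL spam at 0.1 messages/s. The base rate is a
deliberately scaled-down sample of a firehose-scale feed, chosen so
the share of per-second variance the systematic effects explain is
comparable to full-scale streams (roughly half); scaling further down
would leave the same structure buried in Poisson noise, which is a
property of the sample size, not of the phenomenon.

What the generator does **not** emulate: user identities and network
cascade structure (retweets are i.i.d. flags, not a diffusion
process), message semantics and emotional valence, diurnal or
platform-wide nonstationarity, and overlapping-meme interference.
Passing recovery tests therefore shows the estimators are correct
under the stated generative model — not that real streams satisfy that
model.

## Numerical choices and degenerate inputs

* Grid correlations are computed from centred cross-products in one
  vectorised pass (~38k parameter triples against a 600-bin window);
  constant model columns yield undefined correlations and are treated
  as $-\infty$.
* A constant observed series is an error (correlation undefined), as
  are a missing channel, a window shorter than 3 bins, and a series
  shorter than the base-rate tail.
* Max-scaling a window with an all-zero channel is an error rather
  than a silent division by zero.
* `peak_latency` returns the bin-centre time of the *first* maximal
  bin (earliest-peak tie rule); an all-zero channel returns `NA`.
* In the multiscale OLS, rank-deficient columns are dropped by the
  pivoted fit and logged; a design with no usable predictor is an
  error.
* Random-effect structures that fail to converge or are singular fall
  back as described above; the flags are part of the result object.

## Problem sizes used by the test suite

The suite simulates full-length (5400 s) events where turn-level
power matters — 20 seeds for each effect-recovery check, 100 for the
speaker-model type-I simulation, 20 + 50 seed pairs for transfer —
and shorter (400–2400 s) events for plumbing properties, keeping the
whole suite within a few minutes on one CPU. The acceptance script
analyses one full event pair per run. These sizes are the package's
own choice of test conditions, balancing statistical resolution
against run time.

## Known limitations

* Gaussian models on Poisson counts understate tail risk at very low
  rates; at the default rates this is negligible, but the type-I
  tolerance band in the tests is wide for this reason.
* No autocorrelation-robust errors: per-second counts are serially
  dependent within turns, which mixed-model t-values do not fully
  absorb. An AR extension is a natural follow-up.
* Single-kernel attribution: overlapping salient events are summed in
  the design but not deconvolved.
* The substring matcher has no language model: negations, quotes and
  sarcasm all count as mentions. That is faithful to the analyses the
  package operationalises, but worth remembering when interpreting
  channels.
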