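---
title: "Measuring tobacco tax pass-through by price segment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tobacco tax pass-through by price segment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxshift)
library(dplyr)
```

## The problem

When a government raises tobacco duty, manufacturers choose how much of the
increase to pass on. They can absorb part of it (*undershifting*, blunting
the public-health effect of the tax), pass it on exactly, or add their own
increase on top (*overshifting*). Because cigarette brands are organised
into price segments — premium, mid-price, economy and, since the mid-2000s,
ultra-low-price (ULP) — pass-through can differ by segment: overshifting on
expensive brands widens the price gap to the cheapest brands, giving
price-sensitive smokers somewhere to downtrade to instead of quitting.

`taxshift` measures this from brand-level semiannual price/volume panels.
The quantity of interest is the change in **real net-of-tax revenue per
pack**: what the manufacturer and retailer keep after excise and VAT,
expressed in base-year money. If that quantity rises across a window
containing a duty increase, the tax was overshifted; if it falls, the tax
was (partly) absorbed.

## Tax model

UK-style cigarette taxation mixes three components. For a tax-inclusive
retail price $P$ (pence per pack of $k$ sticks), specific duty $s$ (pence
per 1000 sticks), ad valorem rate $a$ and VAT rate $v$:

$$
T(P) \;=\; \underbrace{s\,k/1000}_{\text{specific}}
\;+\; \underbrace{aP}_{\text{ad valorem}}
\;+\; \underbrace{P\,\tfrac{v}{1+v}}_{\text{VAT}},
\qquad N(P) \;=\; P - T(P).
$$

Two conventions are decisions rather than facts, so they are explicit in
the code:

* **Ad valorem base.** The ad valorem duty is levied on the tax-inclusive
  retail selling price (the EU convention). The alternative (pre-VAT base)
  would change the `ad_valorem` component; the regime tibble makes the rate
  explicit so a different base can be encoded as a different rate.
* **VAT extraction.** Input prices are retail, i.e. VAT-inclusive, so VAT
  is extracted as $P\,v/(1+v)$ rather than added.

$N$ is affine in $P$ with slope $1 - a - v/(1+v) > 0$; a regime violating
that inequality leaves non-positive net revenue at every price and is
rejected at construction. Affinity has two useful consequences. First, the
closed-form inverse

$$P = \frac{N_{\text{target}} + s\,k/1000}{1 - a - v/(1+v)}$$

(`price_for_net_revenue()`) is exact, which the simulator exploits. Second,
computing tax on a segment's weighted average price equals the
share-weighted average of per-brand tax bills whenever pack sizes are
uniform — so the conventional "tax on the segment WAP" construction loses
nothing at uniform pack size (a test asserts both the equality and its
failure under mixed 19/20-stick packs).

Regimes are dated: the regime in force at a date is the one with the latest
effective date not after it, with no proration inside an observation
window. A mid-window change (for example a VAT cut dated December) is
picked up by whichever observations fall after it.

## From panel to shifting table

1. **Panel.** Brand-level observations, two per year ("H1" ≈ May/June,
   "H2" ≈ November/December), each with a nominal pack price, pack size and
   whole-market volume share. Each period has one fixed representative date
   (1 June / 1 November; 2005-H2 can be dated 1 October via `oct_2005` to
   mirror a price source that stopped publishing that autumn) so regime and
   deflator lookups are deterministic. Shares of listed brands must sum to
   at most 1; the remainder plus any unassignable brands is carried as an
   explicit "others" mass, never discarded.
2. **Segments.** A brand-to-segment map with optional validity windows; ULP
   assignments default to starting in 2006. Observations outside a brand's
   window are left unassigned (with a warning) rather than guessed.
3. **Weighted average price.** Within each (segment, period),
   $\sum_b w_b P_b / \sum_b w_b$ with whole-market shares renormalised
   within the segment. A segment-period with no positive-share observation
   is a gap, not a zero — the ULP series simply starts in 2006. An
   unweighted mean is available (`weights = "equal"`) for price lists that
   carry no volume data.
4. **Deflation.** Monthly CPI (or RPI) series; an amount observed at date
   $t$ is multiplied by $I_{\text{base}}/I_t$, matching the latest monthly
   value at or before $t$. Missing coverage is an error, never silent
   interpolation. Because deflation is linear, deflating before or after
   subtracting tax is equivalent; tests assert the consistency.
5. **Shifting.** A November-labelled year runs H2 → H2 and splits at the
   intervening H1. Annual duty increases fall in March/April, inside the
   November–May half; May–November contains no duty event. The two
   half-window changes in real net revenue sum *exactly* to the annual
   change (same data path, no re-estimation). Multi-year summaries average
   the yearly changes; classification uses a tolerance of 0.05 pence (half
   the one-decimal reporting precision) around zero.

### Numerical and reporting choices

* Money is held in pence as doubles; rounding happens only at report time,
  to one decimal, **half away from zero** (`round_report()`), since
  round-half-to-even would be surprising in a published-table context.
* Published tables of this kind print yearly changes to one decimal and
  average those printed figures; `use_rounded_years = TRUE` (the default)
  reproduces that arithmetic, while `FALSE` averages at full precision.
  With either choice the multi-year average is reported unrounded and
  rounded only in the final table.
* The brand share filter (`filtered_shift()`) is strict: a threshold of
  0.002 keeps brands with *over* 0.2% of the market at the initial period;
  a brand exactly at the threshold is excluded. A segment emptied by the
  filter is reported as missing.
* The MPPC ("most popular price category") has no official bin definition,
  so prices are binned at a configurable resolution (default 1 penny), the
  winning bin is the one with the largest summed share, ties break to the
  lower price, and the bin is represented by its share-weighted mean price.
  Indices are built on nominal prices and rebased to 100 at the base
  period; growth is the final-over-base ratio.
* Brand-level scatter analyses deflate each brand's own prices (not the
  segment WAP) and summarise with a rank (Spearman) correlation, since the
  relationship of interest is monotone rather than linear and brand panels
  contain outliers; Pearson is available via `method`. A constant variable
  makes the correlation undefined: it is reported as `NA` with a
  `degenerate` flag, never silently dropped.

## The synthetic market generator

No public brand-level price/share panel exists for the study setting (the
real analyses of this kind rest on proprietary scan and survey data), so
the package ships a generator whose ground truth is known *by
construction*:

* Each brand's **real net-of-tax revenue** follows a random walk with
  segment-specific steps: `delta_event` real pence in each window
  containing a duty increase, `drift` real pence otherwise, plus Gaussian
  noise (sd `noise_sd`, default 1 pence). Noise lives on the net-revenue
  scale in pence — the same scale as the classification tolerance — not on
  log price.
* The nominal price is then recovered through the **exact tax inverse**
  under the regime and CPI level of the period. Overshifting by δ is
  therefore exact by construction rather than emergent from a behavioural
  price-setting model; pass-through is a controllable parameter.
* **Shares** follow the multiplicative logit rule
  $w_b \propto w_b^{\text{prev}} \exp(-\beta\, p_b^{\text{real}}/\bar p)$,
  renormalised to the listed-brand mass (1 − `others_share`, held
  constant). β > 0 moves share toward cheaper brands each period.
* Each brand draws from its **own pseudo-random stream** derived from the
  master seed, so enlarging one segment never perturbs other brands'
  trajectories, and the whole scenario is byte-deterministic given the
  seed.

The default scenario (`default_uk_scenario()`) spans 2001–2009 with 16
brands across the four segments (premium ≈ 550p, mid ≈ 500p, economy ≈
450p, ULP ≈ 400p at entry; ULP entering in 2006 with 5% of the market taken
from the incumbents), specific duty rising from 9225 pence per 1000 sticks
by 275 pence each 1 April, 22% ad valorem, VAT 17.5% → 15% (December
2008) → 17.5% (January 2010), and 2% annual CPI inflation with a 2010 base.
The duty-event deltas and off-event drifts default to the observed UK
pattern: overshifting on premium/mid/economy at duty events
(+2.9/+3.9/+2.1 real pence) and absorption on ULP (−3.0) with compensating
off-event ULP increases (+4.3). The downtrading sensitivity β defaults to
0.42, calibrated once so that the ULP market share roughly doubles over
2006–2009 in the default scenario — the generator's design contract — and
initial within-segment brand weights and ±2% price offsets are
deterministic so that brands are distinguishable without extra randomness.

Two properties of the design deserve emphasis:

* **Null-scenario exactness.** With zero noise, zero deltas, zero drift and
  β = 0, every per-segment net-of-tax real change is exactly zero and every
  window classifies as full pass-through — the pipeline adds no numerical
  drift beyond ~1e-12. Real *gross* prices still move, because the nominal
  duty path and VAT changes do; only the net quantity is flat.
* **Composition effects are real, not bugs.** The whole-market ("all")
  aggregate jumps when ULP brands enter mid-span even in a null scenario,
  because adding cheap brands lowers the market average — precisely the
  aggregation problem that motivates monitoring prices *by segment*. Tests
  of null-exactness for the aggregate therefore use a variant with every
  segment present from the start.

`downtrading_scenario()` exists alongside the default because the two
scenarios answer different questions. The default reproduces the observed
per-segment pattern, in which the *economy* segment shows the largest
three-year increases; under the logit share rule economy brands then both
raise prices fastest and gain share, which dilutes the brand-level inverse
relation between price change and share change (negative in roughly nine
out of ten seeds, not ~19 in 20). The downtrading scenario makes the
price-growth gradient monotone in segment price level (event deltas
4/3/2/−3, drifts 2/1.5/1/1 pence) — the configuration in which downtrading
is the designed outcome — and yields the inverse relation in effectively
every seed. The brand-level association property is stated, and tested, on
that scenario.

### What the generator does and does not emulate

It emulates: the semiannual observation calendar; duty events inside the
November–May window; segment structure with late ULP entry; differential
pass-through with noise; VAT regime changes; share drift toward cheaper
brands; an explicit unlisted-brand mass. It does **not** emulate: multiple
inconsistent data sources (panels are internally consistent by
construction; the source-merging code is exercised on hand-built fixtures
instead); behavioural demand or price-setting (pass-through is imposed, not
derived); promotions, pack-size mix shifts within a brand, smuggling or
cross-border substitution; reconstruction of official price-index
methodology (index series are smooth geometric paths). Passing tests
therefore demonstrate that the *measurement pipeline* recovers known
pass-through from data of this shape — not that any behavioural model of
the industry is correct.

## Problem sizes and tolerances used in the checks

The test-suite and the acceptance script run at the scale of the study
design: 16–18 brands, 18 semiannual periods, 3 analysis years (2006–2008,
November-labelled), noise sd 1 pence. Parameter recovery is asserted within
$3\sigma/\sqrt{n_\text{events}}$ with $n_\text{events}=3$; since the
segment WAP averages 3–5 brand noises, the estimator's actual standard
error is roughly $\sigma/(2\sqrt{3})$, so the bound is comfortable but not
vacuous. The downtrading property uses 20 seeds; randomized tax-engine
property tests use 200–300 draws. Everything is deterministic given the
seeds fixed in the tests.

## A worked pass

```{r worked}
sim <- simulate_market(default_uk_scenario(seed = 42))
series <- build_segment_series(sim$panel, sim$schedule, sim$cpi)
shifting_table(series, 2006:2008, sim$schedule)
```

Compare the `nov_may` column with the configured duty-event deltas
(+2.9/+3.9/+2.1/−3.0): duty-event overshifting on the dearer segments and
absorption on ULP are recovered from the generated prices alone. The
index comparison makes the aggregation point:

```{r indices}
glance(compare_indices(sim$panel))
```

and the brand-level scatter summarises downtrading — shown here on the
downtrading scenario, where the inverse relation is the designed outcome
(on the default scenario the same call gives a near-zero correlation, for
the composition reason discussed above):

```{r scatter}
dt <- simulate_market(downtrading_scenario(seed = 42), realized = FALSE)
glance(share_change_vs_price_change(dt$panel, dt$cpi,
                                    "2006-H2", "2009-H2"))
```

## Known limitations

* Only the three-parameter excise structure (specific, ad valorem on the
  retail price, VAT) is expressible; minimum excise floors and other
  product categories are out of scope.
* Whether historical analyses used the duty in force at the observation
  date or at the budget announcement is not generally documented; this
  package uses the observation date throughout.
* Annual survey shares held constant across a year's two price periods (the
  default treatment when semiannual shares are unavailable) smooth
  within-year share dynamics.
* The share rule is a reduced-form drift, not a demand system; elasticities
  and welfare statements are outside the package's claims.
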