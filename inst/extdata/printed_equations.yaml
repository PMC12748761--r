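# Published binomial dummy-variable regressions of the Africa-wide
# factorial simulation output, transcribed verbatim at full printed
# precision (scientific-notation coefficients expanded exactly).
# Responses: yield = g root dry matter per plant; cm = annual cumulative
# CM active stages per plant; cgm = annual cumulative CGM eggs plus
# immature stages per plant. Term means are the printed regressor means
# (interaction columns have their own printed means). t-values, R2, F and
# df are printed metadata from the original Africa-wide fit and are not
# refit here.
equations:
  1:
    response: yield
    intercept: 3464.8
    terms:
      - {name: CM,       vars: [CM],         coef: -1085.0, mean: 0.860, t: -210.1}
      - {name: Al,       vars: [Al],         coef: 958.0,   mean: 0.533, t: 182.1}
      - {name: Ad,       vars: [Ad],         coef: 666.1,   mean: 0.386, t: 25.3}
      - {name: P,        vars: [P],          coef: 378.2,   mean: 0.499, t: 68.7}
      - {name: "Ad:Al",  vars: [Ad, Al],     coef: -687.9,  mean: 0.266, t: -26.1}
      - {name: "Ad:P",   vars: [Ad, P],      coef: -260.5,  mean: 0.253, t: -9.6}
      - {name: "Al:P",   vars: [Al, P],      coef: -317.7,  mean: 0.268, t: -43.3}
      - {name: "Ad:Al:P", vars: [Ad, Al, P], coef: 220.9,   mean: 0.132, t: 8.1}
    r2: 0.171
    f: 9023.1
    df: 350442
  2:
    response: yield
    intercept: 3465.0
    terms:
      - {name: CM,      vars: [CM],     coef: -1091.0, mean: 0.860, t: -209.39}
      - {name: Al,      vars: [Al],     coef: 955.0,   mean: 0.533, t: 202.77}
      - {name: P,       vars: [P],      coef: 596.7,   mean: 0.499, t: 123.9}
      - {name: "Al:P",  vars: [Al, P],  coef: -557.3,  mean: 0.268, t: -94.0}
    r2: 0.155
    f: 16126
    df: 231295
  3:
    response: cm
    intercept: 3661600.0
    terms:
      - {name: Al,      vars: [Al],     coef: -3370000.0, mean: 0.518, t: -211.0}
      - {name: P,       vars: [P],      coef: 313100.0,   mean: 0.495, t: 19.0}
      - {name: "Al:P",  vars: [Al, P],  coef: -491400.0,  mean: 0.259, t: 21.4}
    r2: 0.119
    f: 34083.1
    df: 760116
  4:
    response: yield
    intercept: 3466.8
    terms:
      - {name: CGM,        vars: [CGM],        coef: -1345.0, mean: 0.816,  t: -266.2}
      - {name: Ta,         vars: [Ta],         coef: 508.7,   mean: 0.449,  t: 154.7}
      - {name: Am,         vars: [Am],         coef: 289.0,   mean: 0.439,  t: 87.0}
      - {name: P,          vars: [P],          coef: 488.8,   mean: 0.608,  t: 133.2}
      - {name: "Ta:Am:P",  vars: [Ta, Am, P],  coef: -287.5,  mean: 0.1581, t: -58.8}
    r2: 0.224
    f: 15674.5
    df: 272134
  5:
    response: cgm
    intercept: 80381.0
    terms:
      - {name: Ta,         vars: [Ta],         coef: -104200.0, mean: 0.450, t: -154.4}
      - {name: Am,         vars: [Am],         coef: -51600.0,  mean: 0.439, t: -75.6}
      - {name: P,          vars: [P],          coef: 179100.0,  mean: 0.608, t: 293.3}
      - {name: "Ta:Am",    vars: [Ta, Am],     coef: 310500.0,  mean: 0.291, t: 232.4}
      - {name: "Ta:Am:P",  vars: [Ta, Am, P],  coef: -261800.0, mean: 0.158, t: -283.8}
    r2: 0.303
    f: 23659.0
    df: 272135
  6:
    response: cgm
    intercept: 285830.0
    terms:
      - {name: Ta,       vars: [Ta],      coef: -127400.0, mean: 0.576, t: -191.7}
      - {name: Am,       vars: [Am],      coef: -70350.0,  mean: 0.524, t: -101.4}
      - {name: "Ta:Am",  vars: [Ta, Am],  coef: 67690.0,   mean: 0.288, t: 74.3}
    r2: 0.293
    f: 16459
    df: 119011
# Derived quantities as printed in the source, used for verification only.
printed_derived:
  marginals:
    - {eq: 1, var: CM, value: -1085.0}
    - {eq: 1, var: Al, value: 575.8}
    - {eq: 1, var: Ad, value: 233.1}
    - {eq: 1, var: P,  value: 153.8}
    - {eq: 2, var: Al, value: 676.9}
    - {eq: 2, var: P,  value: 299.7}
    - {eq: 3, var: Al, value: -3613246.0}
    - {eq: 3, var: P,  value: 58555.0}
    - {eq: 4, var: CGM, value: -1345.0}
    - {eq: 4, var: P,  value: 432.1}
    - {eq: 4, var: Ta, value: 432.0}
    - {eq: 4, var: Am, value: 210.5}
    - {eq: 5, var: Ta, value: -37768.0}
    - {eq: 5, var: Am, value: 16496.0}
    - {eq: 5, var: P,  value: 102916.0}
    - {eq: 6, var: Ta, value: -91930.4}
    - {eq: 6, var: Am, value: -31360.5}
  predictions_at_means:
    - {eq: 5, value: 168412.0}
    - {eq: 6, value: 195080.0}
  reductions:
    - {eq: 3, on: [Al, P], mode: endpoint, value: 97.0}
    - {eq: 6, on: [Ta, Am], mode: marginal_vs_intercept, value: 43.0}
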