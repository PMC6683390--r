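# A priori plausibility weights in [0,1] for candidate antibody specificities
# (higher = more plausible). Encodes relative population polymorphism /
# reported-antibody frequency; HPA-4, HPA-6 and HPA-21w alloantibodies are
# essentially unreported in East Asian and most other populations.
specificity,weight
anti-HLA,1.0
anti-HPA-1a,0.90
anti-HPA-1b,0.50
anti-HPA-2a,0.40
anti-HPA-2b,0.60
anti-HPA-3a,0.85
anti-HPA-3b,0.80
anti-HPA-4a,0.05
anti-HPA-4b,0.05
anti-HPA-5a,0.60
anti-HPA-5b,0.70
anti-HPA-6a,0.10
anti-HPA-6b,0.10
anti-HPA-15a,0.55
anti-HPA-15b,0.55
anti-HPA-21wa,0.05
anti-HPA-21wb,0.05
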