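# Gynaecological-cancer query terms used by the control-population
# exclusion rule; multi-word terms match as consecutive normalized words.
ovarian cancer
cancer of the ovary
endometrial cancer
womb cancer
uterine cancer
cervical cancer
cancer of the cervix
vulval cancer
vaginal cancer
fallopian tube cancer
gynaecological cancer
gynecological cancer
ca125 cancer
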