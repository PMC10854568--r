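slide_id,n_anno1,n_anno2,n_agreed
F17-04773,31,31,23
F17-03141,69,89,55
F17-1261,45,46,41
F18-13364,695,517,444
F17-02232,331,264,218
F17-04911,49,58,37
F17-0549,157,142,112
F17-011577,27,29,23
F17-011777,449,367,290
F17-03855,97,87,70
F17-04900,91,86,75
F18-7832,496,401,346
F17-09700,202,187,139
F17-02641,59,48,43
F17-09926,77,71,62
F17-02723,49,52,40
F17-05935,55,46,44
F17-02120,58,53,43
F18-79705,132,99,87
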