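(((((((((bg_04:0.54274,(mk_02:0.129876,rel_02:0.10398):0.571371):0.285009,(mk_01:0.052145,rel_01:0.061034):0.628912):0.277351,bg_03:0.27398):0.127259,bg_01:0.38663):0.25707,bg_06:0.767443):0.190661,bg_05:0.500015):0.127148,bg_02:0.281138):0.277044,bg_08:0.721555):0.167343,bg_07:0.32303);
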