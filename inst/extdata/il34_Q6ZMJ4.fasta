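>IL34_HUMAN bundled human IL-34 precursor (242 aa); signal peptide 1-20
MPRGFTWLRYLGILLGVALGNEPLEMWPLTQNEECTVTGFLRDKLQYRSRLQYMKHYFPI
NYKISVPYEGVFRIANVTRLQRAQVSERELRYLWVLVSLSATESVQDVLLEGHPSWKYLQ
EVETLLLNVQQGLTDVEVSPKVESVLSLLNAPGPNLKLVRPKALLDNCFRVMELLYCSCC
KQSSVLNWQDCEVPSPQSCSPEPSLQYAATQLYPPPPWSPSSPPHSTGSVRPVRAQGEGL
LP
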