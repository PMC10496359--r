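((s7:1.198846435,(s2:0.01494217729,s12:0.01494217729):1.183904257):0.2595442676,(((s15:0.09235906872,s6:0.09235906872):0.7150632845,((s3:0.1518591976,(s11:0.03736964734,s8:0.03736964734):0.1144895502):0.5731979684,(s13:0.104340074,(s4:0.09914540485,(s9:0.01239605074,s10:0.01239605074):0.08674935411):0.005194669179):0.6207170919):0.08236518733):0.3818154583,(s16:1.064840119,((s1:0.6921708638,s5:0.6921708638):0.07563875373,s14:0.7678096175):0.297030501):0.1243976931):0.2691528907);
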