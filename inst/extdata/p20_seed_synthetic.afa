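>seed01 synthetic p20 seed row
HRGGAENYHNNDKYDTAHPGPTSNGQQQQKNDKYDAYGDEEPDKTDYYSRRTHEFSGHGHGPSTAENHHETHYYQNYEYTNSNKYDRANAQYKERRHQQAAGGGDHPDTDTCHSERQKNQGNDGANEYDGEHYGSEPYTHTPESTSGYTQ
>seed02 synthetic p20 seed row
HRGGAENYHNDDKYDEAHPGPTSNGQQQPKNDKYDAYGDEYPDKTDYYNRRTHEFSGHGHGPSTAENHHETHYYQNYEYTNSNKYDRGNKTYKERRHTQAAGGGDHPDTDTCHSERQKNYGNYGANEYDGEHYGSEAYTHTPESTSGYTN
>seed03 synthetic p20 seed row
HRGGAENYHNDDRYDEAHPHPTSNGQQQQKNDKYDAYGDEEPDGTDYYSRRGHEFSGHGHGPSEAENHHETHYYQNYEYTNSNKYDRYNAQYKERRHQQAAGGGDHSDTDTCHSERQKNYGNDGANEYDGEHAGSEAYTHTPESTKGYTN
>seed04 synthetic p20 seed row
KRGGAENYHNDDKYDEAHPGPTSNGNQQQKNDKYDANGDEEPDKTDYYSRRTHEFSGHGHGPSTAENHHETHYYQNYEYRNSNKYDRYNAQYPERRHQQAAGGGDHPDTDTCHSERQKNYGNDGANEYHGEHYGSEAYTHTPESGSGYTE
>seed05 synthetic p20 seed row
HRGGASNYHNDDKYDEAHP---SPAQQQQKNDKYDAYGDEEPDKTDYYSRRTHEFSGHGHGPSTAENHHETHYKQNYESTNSNKYDRYNAQYKERRHDQAAGGGDHPDTDTCHSERQKNYGNDGANGYDGEHYGSEAYTHTPESTSGYTN
>seed06 synthetic p20 seed row
HRGGAEKYHNDDKYDEAHPGPTSNGQQQQKPDKYPAYGDEEPHKTDYYSRRTHEFSGHGHGPSTAENHHETHNYQNYEYTNSNKYDQYNAQYKERRHQQAAGGGDHPDTDTCHSERQKNYGNDGANEYDGSHYGSEAYTHTPESTSGYTN
>seed07 synthetic p20 seed row
HRGGAENYHNDDKYDEAHPGPTSNGQQQQKNDKYDAYGDEEPDKTDYYSRRTHEFSGHGHGPSTAENHHETHYYQNYEQTNQNKYDRYNAQYKERRHSQAAGGNDHPDTDTCHSERQKRYANDGANEYDGEHYG--ADTHTPESTSGYTN
>seed08 synthetic p20 seed row
HRGGAENYHNDDKYDEAHPGPTSNGQQQEGNDKYDAYGDEEPDKTDYYSRSTHEFSGHGHGPSTAENHHETTYYQNYEYTNSNKYDRYNAQYKERRHQQAAGGGDHPDTDTCHSERQKNYGNDGANEYPGEHNGSEAYTHTPTSTSGYTN
>seed09 synthetic p20 seed row
HRGGAENYHNDDKYDEAHPGPTENGQQQQKNDKYAAYGDEEPDKTDYYSRRTHEFSGYGHGPSEAENHHETGYYQNYEYTNSNKYDRYNAQYKERRHQQAYGGGDHPDTDTSHSERQKNYGNDGANEYDGEHYQSEEDTHTPESTSGYTN
>seed10 synthetic p20 seed row
HRGGASNYHNDDKYDEAHPGPTSNGQQQQKNDKYDAYGDEEPDHTDYYSRRTHEFSGYGHGPSTAENHHPTHYYQNYEYTNSNGYDRYNAQYKERRHQQAAGGGDHPDTDTNHSERQKNYGNDGANEDTGEHYKSEAYQHTPESTSGYTN
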